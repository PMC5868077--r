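#' Trapezoidal / triangular membership function
#'
#' Membership functions are stored as four breakpoints \code{(a, b, c, d)}:
#' zero below \code{a}, linear rise on \code{[a, b]}, one on \code{[b, c]},
#' linear fall on \code{[c, d]}, zero above \code{d}. A triangle has
#' \code{b == c}; a shoulder at a universe edge has \code{a == b} or
#' \code{c == d}.
#'
#' @param a,b,c,d Breakpoints, \code{a <= b <= c <= d}.
#' @param label Linguistic label (e.g. \code{"NB"}, \code{"PS"}).
#' @return An object of class \code{membership_fn}.
#' @export
membership_fn <- function(a, b, c, d, label = "") {
  stopifnot(is.numeric(c(a, b, c, d)), a <= b, b <= c, c <= d)
  structure(list(a = a, b = b, c = c, d = d, label = label),
            class = "membership_fn")
}

#' Triangular membership function
#'
#' Convenience wrapper around [membership_fn()] with \code{peak} as both
#' inner breakpoints. \code{left == peak} or \code{peak == right} gives a
#' degenerate shoulder, allowed at universe edges.
#'
#' @param left,peak,right Breakpoints in universe units.
#' @param label Linguistic label.
#' @export
triangular_mf <- function(left, peak, right, label = "") {
  membership_fn(left, peak, peak, right, label)
}

#' Evaluate a membership function
#'
#' @param mf A \code{membership_fn}.
#' @param x Numeric vector.
#' @return Membership degrees in \[0, 1\].
#' @export
mf_degree <- function(mf, x) {
  out <- numeric(length(x))
  rise <- x >= mf$a & x < mf$b
  flat <- x >= mf$b & x <= mf$c
  fall <- x > mf$c & x <= mf$d
  if (mf$b > mf$a) out[rise] <- (x[rise] - mf$a) / (mf$b - mf$a)
  out[flat] <- 1
  if (mf$d > mf$c) out[fall] <- (mf$d - x[fall]) / (mf$d - mf$c)
  out
}

#' Fuzzy partition of a universe of discourse
#'
#' An ordered set of membership functions covering \code{universe}. The
#' default partitions built by [input_partition()] and [output_partition()]
#' are Ruspini partitions: memberships sum to one at every point of the
#' universe, so some rule always fires.
#'
#' @param universe Length-2 numeric, \code{c(min, max)}.
#' @param mfs List of \code{membership_fn}, in label order.
#' @return An object of class \code{fuzzy_partition}.
#' @export
fuzzy_partition <- function(universe, mfs) {
  stopifnot(length(universe) == 2, universe[1] < universe[2], length(mfs) >= 1)
  labels <- vapply(mfs, function(m) m$label, "")
  if (anyDuplicated(labels)) stop("duplicate membership labels")
  structure(list(universe = universe, mfs = mfs, labels = labels),
            class = "fuzzy_partition")
}

#' Seven-set input partition for error and error-derivative
#'
#' Uniform Ruspini partition with triangular sets labelled
#' NB, NM, NES, ZE, PS, PM, PB (negative big ... positive big), peaks evenly
#' spaced over \code{[lo, hi]}, degenerate shoulders at the edges.
#'
#' @param lo,hi Universe bounds, degrees.
#' @export
input_partition <- function(lo = -10, hi = 10) {
  stopifnot(lo < hi)
  labels <- c("NB", "NM", "NES", "ZE", "PS", "PM", "PB")
  pk <- seq(lo, hi, length.out = 7)
  mfs <- lapply(1:7, function(i) {
    triangular_mf(if (i == 1) pk[1] else pk[i - 1], pk[i],
                  if (i == 7) pk[7] else pk[i + 1], labels[i])
  })
  fuzzy_partition(c(lo, hi), mfs)
}

#' Three-set output partition for the PWM duty ratio
#'
#' PS / PM / PB on the duty universe \[0, 1\] with peaks at
#' \code{peaks} (default 0.15 / 0.50 / 0.85) and flat shoulders at the
#' universe edges, forming a Ruspini partition.
#'
#' @param peaks Numeric length 3, increasing, inside \[0, 1\].
#' @export
output_partition <- function(peaks = c(0.15, 0.5, 0.85)) {
  stopifnot(length(peaks) == 3, all(diff(peaks) > 0),
            peaks[1] >= 0, peaks[3] <= 1)
  fuzzy_partition(c(0, 1), list(
    membership_fn(0, 0, peaks[1], peaks[2], "PS"),
    membership_fn(peaks[1], peaks[2], peaks[2], peaks[3], "PM"),
    membership_fn(peaks[2], peaks[3], 1, 1, "PB")))
}

#' Rule base for the intensity controller
#'
#' The 7 x 7 rule table mapping (error, error change) label pairs to output
#' duty labels. Rows index the error-change label, columns the error label;
#' \code{orientation = "de_rows"} is the default reading, \code{"e_rows"}
#' transposes it.
#'
#' @param table Character 7 x 7 matrix with entries in PS/PM/PB, dimnames
#'   the seven input labels. Default: the controller's standard rule set.
#' @param orientation \code{"de_rows"} (rows = error change) or
#'   \code{"e_rows"}.
#' @return Object of class \code{rule_table}: a matrix with rows = error
#'   change, columns = error, after resolving orientation.
#' @export
rule_table <- function(table = default_rules(), orientation = c("de_rows", "e_rows")) {
  orientation <- match.arg(orientation)
  labels <- c("NB", "NM", "NES", "ZE", "PS", "PM", "PB")
  stopifnot(is.matrix(table), all(dim(table) == c(7, 7)))
  if (is.null(dimnames(table))) dimnames(table) <- list(labels, labels)
  stopifnot(identical(rownames(table), labels),
            identical(colnames(table), labels))
  if (!all(table %in% c("PS", "PM", "PB")))
    stop("rule outputs must be PS, PM or PB")
  if (orientation == "e_rows") table <- t(table)
  structure(table, class = c("rule_table", class(table)))
}

#' Standard rule set
#'
#' Rows = error change (NB..PB top to bottom), columns = error (NB..PB left
#' to right). Large positive error with rising error demands the big output;
#' falling error backs the intensity off.
#'
#' @keywords internal
#' @export
default_rules <- function() {
  labels <- c("NB", "NM", "NES", "ZE", "PS", "PM", "PB")
  matrix(c(
    "PS", "PS", "PS", "PS", "PS", "PS", "PM",
    "PS", "PS", "PS", "PS", "PS", "PM", "PM",
    "PS", "PS", "PS", "PS", "PS", "PM", "PM",
    "PM", "PM", "PS", "PS", "PM", "PM", "PM",
    "PM", "PM", "PM", "PB", "PB", "PB", "PB",
    "PM", "PM", "PB", "PB", "PB", "PB", "PB",
    "PM", "PB", "PB", "PB", "PB", "PB", "PB"),
    nrow = 7, byrow = TRUE, dimnames = list(labels, labels))
}

#' Fuzzify a crisp value
#'
#' Values outside the universe are clamped to its bounds before evaluating
#' the membership functions, so an out-of-range input behaves like the
#' nearest bound.
#'
#' @param x Scalar in universe units.
#' @param partition A \code{fuzzy_partition}.
#' @return Named membership vector, one entry per set.
#' @export
fuzzify <- function(x, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"), length(x) == 1,
            is.finite(x))
  if (length(partition$mfs) == 0) stop("empty partition")
  x <- min(max(x, partition$universe[1]), partition$universe[2])
  mu <- vapply(partition$mfs, mf_degree, numeric(1), x = x)
  names(mu) <- partition$labels
  mu
}

#' Mamdani inference over the rule base
#'
#' Each rule (e label, de label) fires with strength
#' \code{min(mu_e, mu_de)}; rules sharing an output label are combined by
#' max; the aggregate output membership is the pointwise max of the output
#' sets clipped at their firing strengths.
#'
#' @param mu_e,mu_de Named membership vectors from [fuzzify()].
#' @param rules A [rule_table()].
#' @param output Output \code{fuzzy_partition}.
#' @return Object of class \code{fuzzy_aggregate}: firing strengths per
#'   output label plus the output partition.
#' @export
fuzzy_infer <- function(mu_e, mu_de, rules = rule_table(),
                        output = output_partition()) {
  stopifnot(inherits(rules, "rule_table"))
  if (any(is.na(rules))) stop("rule table is not total")
  strength <- stats::setNames(numeric(length(output$labels)), output$labels)
  for (i in seq_along(mu_de)) {
    if (mu_de[i] == 0) next
    for (j in seq_along(mu_e)) {
      s <- min(mu_e[j], mu_de[i])
      if (s == 0) next
      lab <- rules[names(mu_de)[i], names(mu_e)[j]]
      strength[lab] <- max(strength[lab], s)
    }
  }
  structure(list(strength = strength, output = output),
            class = "fuzzy_aggregate")
}

#' Evaluate an aggregated output membership function
#'
#' @param aggregate A \code{fuzzy_aggregate} from [fuzzy_infer()].
#' @param x Numeric vector on the output universe.
#' @export
aggregate_degree <- function(aggregate, x) {
  mu <- numeric(length(x))
  for (i in seq_along(aggregate$output$mfs)) {
    s <- aggregate$strength[i]
    if (s == 0) next
    mu <- pmax(mu, pmin(s, mf_degree(aggregate$output$mfs[[i]], x)))
  }
  mu
}

#' Centroid (center-of-area) defuzzification
#'
#' Computes \code{integral(x mu(x)) / integral(mu(x))} over the output
#' universe by trapezoidal quadrature on \code{resolution} points. When no
#' rule fires (aggregate identically zero) the previous duty is held.
#'
#' @param aggregate A \code{fuzzy_aggregate}.
#' @param resolution Number of quadrature points (>= 101).
#' @param prev Duty to hold when the aggregate is identically zero.
#' @return Duty ratio in \[0, 1\].
#' @export
defuzzify_centroid <- function(aggregate, resolution = 1001, prev = 0) {
  stopifnot(resolution >= 101)
  if (all(aggregate$strength == 0)) return(prev)
  u <- aggregate$output$universe
  x <- seq(u[1], u[2], length.out = resolution)
  mu <- aggregate_degree(aggregate, x)
  w <- rep(1, resolution); w[c(1, resolution)] <- 0.5  # trapezoid weights
  sum(w * x * mu) / sum(w * mu)
}

#' Fuzzy intensity controller configuration
#'
#' @param theta_req Reference maximum swing dorsiflexion, degrees. The
#'   default 4.9 is the normal maximum ankle dorsiflexion of healthy
#'   walking.
#' @param e_universe Error universe, degrees.
#' @param de_universe Error-change universe, degrees. Deliberately wide:
#'   cycle-to-cycle error differences are noisy and the rule base reacts
#'   aggressively to them, so the derivative channel is desensitised and
#'   contributes only for abrupt changes.
#' @param output_peaks PS/PM/PB duty peaks on \[0, 1\].
#' @param rules A [rule_table()].
#' @param defuzz_resolution Quadrature points for [defuzzify_centroid()].
#' @param amplitude_cap Maximum deliverable pulse amplitude, mA (<= 120,
#'   the stimulator limit).
#' @return Object of class \code{flc_config}.
#' @export
flc_config <- function(theta_req = 4.9,
                       e_universe = c(-10, 10),
                       de_universe = c(-60, 60),
                       output_peaks = c(0.15, 0.5, 0.85),
                       rules = rule_table(),
                       defuzz_resolution = 1001,
                       amplitude_cap = 120) {
  stopifnot(amplitude_cap > 0, amplitude_cap <= 120,
            theta_req > e_universe[1], theta_req < e_universe[2] + 4.9 + 90)
  structure(list(
    theta_req = theta_req,
    e_partition = input_partition(e_universe[1], e_universe[2]),
    de_partition = input_partition(de_universe[1], de_universe[2]),
    output = output_partition(output_peaks),
    rules = rules,
    defuzz_resolution = defuzz_resolution,
    amplitude_cap = amplitude_cap), class = "flc_config")
}

#' Initial controller state
#'
#' Duty starts at zero (the first walking cycle is unstimulated; the first
#' stimulated cycle uses the first controller output) and the error change
#' on the first update is zero.
#'
#' @param config An [flc_config()].
#' @export
flc_state <- function(config = flc_config()) {
  structure(list(cycle = 0L, e = NA_real_, de = NA_real_,
                 duty = 0, amplitude = 0,
                 amplitude_cap = config$amplitude_cap),
            class = "flc_state")
}

#' Cycle-to-cycle intensity update
#'
#' Runs once per completed gait cycle. The tracking error is
#' \code{e = theta_req - theta_a} (positive when dorsiflexion falls short of
#' the reference), its change \code{de = e_k - e_(k-1)} (zero on the first
#' cycle). The duty ratio is the centroid of the Mamdani inference and the
#' commanded amplitude is \code{duty * amplitude_cap}, clamped.
#'
#' A non-finite \code{theta_a} (e.g. a dropped cycle) leaves the state
#' unchanged apart from the cycle counter, with a warning.
#'
#' @param state An [flc_state()].
#' @param theta_a Measured maximum swing dorsiflexion for the completed
#'   cycle, degrees.
#' @param config An [flc_config()].
#' @return Updated \code{flc_state}.
#' @export
update_intensity <- function(state, theta_a, config = flc_config()) {
  stopifnot(inherits(state, "flc_state"))
  if (!is.finite(theta_a)) {
    warning("non-finite theta_a: cycle skipped, intensity held")
    state$cycle <- state$cycle + 1L
    return(state)
  }
  e <- config$theta_req - theta_a
  de <- if (is.na(state$e)) 0 else e - state$e
  agg <- fuzzy_infer(fuzzify(e, config$e_partition),
                     fuzzify(de, config$de_partition),
                     config$rules, config$output)
  duty <- defuzzify_centroid(agg, config$defuzz_resolution, prev = state$duty)
  duty <- min(max(duty, 0), 1)
  state$cycle <- state$cycle + 1L
  state$e <- e
  state$de <- de
  state$duty <- duty
  state$amplitude <- min(max(duty * state$amplitude_cap, 0), state$amplitude_cap)
  state
}
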