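#' Configuration of the latent-severity respondent generator
#'
#' The simulator draws each household's food-insecurity severity from a
#' latent trait and generates item responses from a two-parameter logistic
#' item-response model: severity is
#' `theta = mu + sum(covariate_effect * flags) + sigma * N(0,1)`, and item
#' `i` is affirmed with probability `plogis(discrimination * (theta -
#' thresholds[i]))`.  Ordered item thresholds reproduce the canonical
#' severity sequence of household food insecurity (worry first, whole days
#' without food last); demographic risk factors shift severity upward;
#' frequency follow-ups honour the skip pattern (item 5 is generated only
#' when item 4 is affirmed, item 10 only when item 9 is).
#'
#' The shipped defaults (see `inst/extdata/generator-default.yaml`) are a
#' qualitative calibration: thresholds ordered `b1 < b3 < b2 < b4 = b5 =
#' b7 < b6 < b8 < b9 = b10` so that the per-item affirmation ranking among
#' the food insecure matches the published instrument ordering, an overall
#' 10-item food-insecurity prevalence in the 10-20% band, and elevated
#' prevalence in the low-income, welfare and not-living-with-spouse
#' subgroups.  They are not a fit to any survey dataset.
#'
#' @param n Number of respondents to generate by default.
#' @param seed Integer seed; every simulation is fully reproducible from
#'   it.
#' @param ... Overrides for any default field: `mu`, `sigma` (latent
#'   location/scale, `sigma > 0`), `discrimination` (slope `a >= 0`;
#'   `Inf` gives the deterministic Guttman limit), `thresholds` (numeric,
#'   10 per-item severity cut-points), `covariate_prevalence` and
#'   `covariate_effect` (named, one entry per demographic flag),
#'   `single_item_threshold`, and `often_shift` (severity excess over an
#'   item's threshold above which an affirmed trichotomous item reads
#'   "often true" rather than "sometimes true"; presentation only, never
#'   affects a score).
#' @return A validated `generator_config` object (a list).
#' @examples
#' cfg <- generator_config(n = 100, seed = 42)
#' cfg$thresholds
#' @export
generator_config <- function(n = 303, seed = NULL, ...) {
  cfg <- default_generator_values()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) {
    if (nm %in% c("covariate_prevalence", "covariate_effect")) {
      v <- unlist(dots[[nm]])
      bad <- setdiff(names(v), .demographic_cols)
      if (length(bad))
        stop("unknown demographic in ", nm, ": ", paste(bad, collapse = ", "),
             call. = FALSE)
      cfg[[nm]][names(v)] <- v
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg$n <- n
  cfg$seed <- seed
  validate_generator_config(cfg)
}

default_generator_values <- function() {
  path <- system.file("extdata", "generator-default.yaml", package = "hfssm",
                      mustWork = TRUE)
  raw <- yaml::yaml.load_file(path)
  raw$thresholds <- as.numeric(unlist(raw$thresholds))
  raw$covariate_prevalence <- unlist(raw$covariate_prevalence)[.demographic_cols]
  raw$covariate_effect <- unlist(raw$covariate_effect)[.demographic_cols]
  raw$discrimination <- as.numeric(raw$discrimination)
  raw
}

validate_generator_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n), length(cfg$n) == 1L, cfg$n >= 0,
            cfg$n == floor(cfg$n))
  if (!is.null(cfg$seed))
    stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (!is.numeric(cfg$sigma) || length(cfg$sigma) != 1L || cfg$sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  if (!is.numeric(cfg$discrimination) || length(cfg$discrimination) != 1L ||
      cfg$discrimination < 0)
    stop("'discrimination' must be a scalar >= 0 (Inf allowed)", call. = FALSE)
  if (length(cfg$thresholds) != 10L || anyNA(cfg$thresholds))
    stop("'thresholds' must be 10 numeric cut-points", call. = FALSE)
  for (nm in c("covariate_prevalence", "covariate_effect")) {
    v <- cfg[[nm]]
    if (length(v) != 5L || !setequal(names(v), .demographic_cols) || anyNA(v))
      stop("'", nm, "' must be named over the five demographics",
           call. = FALSE)
  }
  if (any(cfg$covariate_prevalence < 0 | cfg$covariate_prevalence > 1))
    stop("covariate prevalences must lie in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(cfg$mu), is.numeric(cfg$single_item_threshold),
            is.numeric(cfg$often_shift), cfg$often_shift >= 0)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Latent-severity respondent generator\n")
  cat(sprintf("  n = %d, seed = %s\n", x$n,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  cat(sprintf("  severity: mu = %g, sigma = %g, discrimination = %g\n",
              x$mu, x$sigma, x$discrimination))
  cat("  thresholds:", paste(format(x$thresholds), collapse = " "), "\n")
  cat(sprintf("  single-item threshold = %g\n", x$single_item_threshold))
  cat("  covariates (prevalence, severity shift):\n")
  for (d in .demographic_cols)
    cat(sprintf("    %-24s %.2f  %+.2f\n", d, x$covariate_prevalence[[d]],
                x$covariate_effect[[d]]))
  invisible(x)
}

.item_prob <- function(theta, b, a) {
  if (is.infinite(a)) as.numeric(theta > b) else stats::plogis(a * (theta - b))
}

#' Simulate survey respondents
#'
#' Generates `n` respondents under a [generator_config()]: demographic
#' flags are drawn independently with their configured prevalences,
#' latent severity from the covariate-shifted normal, item affirmations
#' from the two-parameter logistic model with skip-pattern coupling, and
#' the single-item answer from its own severity cut-point.  The same seed
#' always yields byte-identical output.
#'
#' @param cfg A `generator_config`.
#' @param n Number of respondents (defaults to `cfg$n`).
#' @param seed Seed (defaults to `cfg$seed`); required.
#' @return Data frame of records in the package's standard layout
#'   (`q1`..`q10`, `single_item`, five logical demographic columns) plus
#'   the latent severity `theta`, retained so simulations can serve as
#'   test oracles.  [write_records()] drops `theta`.
#' @examples
#' head(simulate_respondents(generator_config(n = 5, seed = 7)))
#' @export
simulate_respondents <- function(cfg, n = cfg$n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(seed)) stop("a seed is required for simulation", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)

  ## fixed draw order: flags, severity noise, item uniforms, single item
  flags <- matrix(stats::runif(n * 5L) <
                    rep(cfg$covariate_prevalence[.demographic_cols], each = n),
                  nrow = n, ncol = 5L,
                  dimnames = list(NULL, .demographic_cols))
  theta <- cfg$mu +
    as.numeric(flags %*% cfg$covariate_effect[.demographic_cols]) +
    cfg$sigma * stats::rnorm(n)
  u <- matrix(stats::runif(n * 10L), nrow = n, ncol = 10L)
  u_single <- stats::runif(n)

  a <- cfg$discrimination
  p <- vapply(1:10, function(i) .item_prob(theta, cfg$thresholds[i], a),
              numeric(n))
  p <- matrix(p, nrow = n, ncol = 10L)
  affirm <- u < p
  affirm[, 5L] <- affirm[, 4L] & affirm[, 5L]   # follow-up skip pattern
  affirm[, 10L] <- affirm[, 9L] & affirm[, 10L]

  often <- vapply(1:10, function(i) theta > cfg$thresholds[i] + cfg$often_shift,
                  logical(n))
  often <- matrix(often, nrow = n, ncol = 10L)

  rec <- data.frame(matrix(nrow = n, ncol = 0L))
  for (i in 1:3)
    rec[[paste0("q", i)]] <- ifelse(affirm[, i],
                                    ifelse(often[, i], "often_true", "sometimes_true"),
                                    "never_true")
  for (i in c(4L, 6L, 7L, 8L, 9L))
    rec[[paste0("q", i)]] <- ifelse(affirm[, i], "yes", "no")
  for (fu in list(c(4L, 5L), c(9L, 10L))) {
    i <- fu[2L]
    rec[[paste0("q", i)]] <- ifelse(!affirm[, fu[1L]], "na",
                             ifelse(affirm[, i],
                                    ifelse(often[, i], "almost_every_month", "some_months"),
                                    "only_1_or_2_months"))
  }
  p_single <- .item_prob(theta, cfg$single_item_threshold, a)
  rec$single_item <- ifelse(u_single < p_single, "yes", "no")
  rec <- rec[, .instrument_cols]
  for (d in .demographic_cols) rec[[d]] <- flags[, d]
  rec$theta <- theta
  rec
}

## ---- population-level (quadrature) oracle ----------------------------------

## Count distributions per generative unit, conditional on every item of
## `constrained` (screener items) being unaffirmed.  Units are the six
## independent items and the two parent/child follow-up pairs, whose joint
## count given theta is trinomial (0, parent only, parent and child).
## Each element is an L x (k+1) matrix of unnormalised probabilities:
## column j holds P(unit count = j - 1 and unit's constrained items all 0)
## at each of the L theta values.
.unit_dists <- function(p, constrained = integer(0)) {
  pairs <- list(c(4L, 5L), c(9L, 10L))
  singles <- c(1L, 2L, 3L, 6L, 7L, 8L)
  dists <- list()
  for (i in singles) {
    dists[[length(dists) + 1L]] <-
      if (i %in% constrained) cbind(1 - p[, i])
      else cbind(1 - p[, i], p[, i])
  }
  for (pr in pairs) {
    pp <- p[, pr[1L]]; pc <- p[, pr[2L]]
    d <- if (pr[1L] %in% constrained) cbind(1 - pp)  # parent 0 forces child 0
         else if (pr[2L] %in% constrained) cbind(1 - pp, pp * (1 - pc))
         else cbind(1 - pp, pp * (1 - pc), pp * pc)
    dists[[length(dists) + 1L]] <- d
  }
  dists
}

## convolve unit count distributions (rows = theta values)
.convolve_units <- function(dists) {
  acc <- matrix(1, nrow = nrow(dists[[1L]]), ncol = 1L)
  for (d in dists) {
    out <- matrix(0, nrow = nrow(acc), ncol = ncol(acc) + ncol(d) - 1L)
    for (j in seq_len(ncol(d)))
      out[, j:(j + ncol(acc) - 1L)] <- out[, j:(j + ncol(acc) - 1L)] +
        d[, j] * acc
    acc <- out
  }
  acc
}

#' Population operating characteristics of a screener
#'
#' Computes the exact population-level sensitivity, specificity, accuracy
#' and reference prevalence of an OR-rule screener under a generator
#' configuration, by numerical integration over the latent severity.
#' Items are conditionally independent given severity (the follow-up
#' pairs 4/5 and 9/10 are handled jointly), so the per-severity
#' probability of any score/screener event is a product-convolution; the
#' marginal is a 32-component normal mixture over the demographic flag
#' combinations.  In the deterministic Guttman limit (infinite
#' discrimination) responses are piecewise constant in severity, and the
#' quadrature reduces to exact mixture-CDF mass on the inter-threshold
#' intervals.  This is the recovery target that empirical estimates from
#' [simulate_respondents()] converge to.
#'
#' @param cfg A `generator_config`.
#' @param items Screener item ids.
#' @param reference_threshold Reference cut-point, default 3.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `prevalence`, on the percentage scale.
#' @examples
#' population_diagnostics(generator_config(n = 1, seed = 1), items = c(1, 3))
#' @export
population_diagnostics <- function(cfg, items, reference_threshold = 3L) {
  stopifnot(inherits(cfg, "generator_config"))
  items <- as.integer(items)
  if (length(items) == 0L || any(items < 1L | items > 10L))
    stop("'items' must be a non-empty subset of 1..10", call. = FALSE)
  r <- as.integer(reference_threshold)

  combos <- as.matrix(expand.grid(rep(list(0:1), 5L)))
  colnames(combos) <- .demographic_cols
  prev <- cfg$covariate_prevalence[.demographic_cols]
  w <- apply(combos, 1L, function(f) prod(ifelse(f == 1, prev, 1 - prev)))
  shift <- as.numeric(combos %*% cfg$covariate_effect[.demographic_cols])

  mix_density <- function(theta)
    colSums(w * vapply(theta, function(t)
      stats::dnorm(t, mean = cfg$mu + shift, sd = cfg$sigma), numeric(32L)))

  if (is.infinite(cfg$discrimination)) {
    ## Guttman limit: responses are step functions of severity, so the
    ## confusion cells are exact mixture-CDF masses on the intervals
    ## between the ordered thresholds (threshold points carry no mass).
    breaks <- sort(unique(cfg$thresholds))
    lo <- c(-Inf, breaks)
    hi <- c(breaks, Inf)
    mid <- ifelse(is.finite(lo) & is.finite(hi), (lo + hi) / 2,
                  ifelse(is.finite(hi), hi - 1, lo + 1))
    mass <- vapply(seq_along(mid), function(k)
      sum(w * (stats::pnorm(hi[k], cfg$mu + shift, cfg$sigma) -
               stats::pnorm(lo[k], cfg$mu + shift, cfg$sigma))), numeric(1))
    cells <- c(tp = 0, fn = 0, tn = 0, fp = 0)
    for (k in seq_along(mid)) {
      affirm <- mid[k] > cfg$thresholds
      affirm[5] <- affirm[4] && affirm[5]
      affirm[10] <- affirm[9] && affirm[10]
      ref_pos <- sum(affirm) >= r
      scr_pos <- any(affirm[items])
      cell <- if (ref_pos && scr_pos) "tp" else if (ref_pos) "fn" else
        if (scr_pos) "fp" else "tn"
      cells[cell] <- cells[cell] + mass[k]
    }
    quad <- cells
  } else quad <- {

  rates <- function(theta) {
    p <- vapply(1:10, function(i)
      .item_prob(theta, cfg$thresholds[i], cfg$discrimination),
      numeric(length(theta)))
    p <- matrix(p, nrow = length(theta), ncol = 10L)
    full <- .convolve_units(.unit_dists(p))
    scr_neg <- .convolve_units(.unit_dists(p, constrained = items))
    tail_ge <- function(d) if (ncol(d) <= r) rep(0, nrow(d)) else
      rowSums(d[, (r + 1L):ncol(d), drop = FALSE])
    ref_pos <- tail_ge(full)                 # P(reference insecure | theta)
    fn <- tail_ge(scr_neg)                   # P(screener -, reference +)
    neg <- rowSums(scr_neg)                  # P(screener -)
    cbind(tp = ref_pos - fn, fn = fn, tn = neg - fn,
          fp = (1 - neg) - (ref_pos - fn))
  }

  vapply(c("tp", "fn", "tn", "fp"), function(q) {
    res <- stats::integrate(function(t) mix_density(t) * rates(t)[, q],
                            lower = -Inf, upper = Inf,
                            rel.tol = 1e-10, abs.tol = 1e-12,
                            subdivisions = 500L, stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected"))
      stop("quadrature did not converge: ", res$message, call. = FALSE)
    res$value
  }, numeric(1))
  }

  total <- sum(quad)
  if (abs(total - 1) > 1e-6)
    stop("quadrature did not converge (cell probabilities sum to ",
         format(total), ")", call. = FALSE)
  pos <- quad[["tp"]] + quad[["fn"]]
  neg <- quad[["tn"]] + quad[["fp"]]
  list(sensitivity = 100 * quad[["tp"]] / pos,
       specificity = 100 * quad[["tn"]] / neg,
       accuracy = 100 * (quad[["tp"]] + quad[["tn"]]),
       prevalence = 100 * pos)
}
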