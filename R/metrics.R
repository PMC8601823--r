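## metrics_eval: Dice scoring, confidence intervals, and the
## initialization-sensitivity / convergence experiment harness.

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical matrices of one shape.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Mean and 90% confidence half-width
#'
#' Student-t interval `mean +/- t(0.95, n-1) * s / sqrt(n)`.
#'
#' @param values numeric vector, length >= 2.
#' @return named vector `(mean, half_width)`.
#' @export
ci90 <- function(values) {
  n <- length(values)
  if (n < 2) stop("ci90 needs at least two values")
  c(mean = mean(values),
    half_width = qt(0.95, n - 1) * sd(values) / sqrt(n))
}

.methodTable <- data.frame(
  method = c("FLS-UM", "FLS-MS", "ALRLS-UM", "ALRLS-MS"),
  energy = c("UM", "MS", "UM", "MS"),
  compensate = c(FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Initialization-sensitivity experiment
#'
#' Runs every (case, method, radius) combination: for each phantom the
#' initial contour is a circle at the deepest air point, at each of the
#' requested radii (clipped, with a warning, to the largest circle that
#' fits).  Dice is scored against the full-cavity ground truth; failed runs
#' keep their last contour.  Per-method Dice is averaged over the radii as
#' well as reported per row.  Byte-identical tables for identical seeds.
#'
#' @param cohort list of [PhantomSample].
#' @param methods subset of `c("FLS-UM", "FLS-MS", "ALRLS-UM", "ALRLS-MS")`.
#' @param radii initial radii in pixels.
#' @param cfg base [RunConfig]; energy model and compensation flag are
#'   overridden per method.
#' @param model trained [PatchCNN] (needed for the ALRLS methods).
#' @return list with `rows` (one data.frame row per run: case, method,
#'   radius, dice, iterations, status) and `summary` (per-method mean, sd,
#'   and 90% CI over the pooled per-run Dice, plus the per-case
#'   radius-spread sd).
#' @export
runSensitivity <- function(cohort, methods = c("FLS-UM", "ALRLS-UM"),
                           radii = c(3, 5, 7, 9, 11), cfg = runConfig(),
                           model = NULL) {
  stopifnot(all(methods %in% .methodTable$method))
  rows <- list()
  for (ci in seq_along(cohort)) {
    s <- cohort[[ci]]
    sp <- seedPoint(s)
    truth <- cavityMask(s)
    clsCache <- new.env(parent = emptyenv())  # shared across radii/methods
    for (m in methods) {
      mrow <- .methodTable[.methodTable$method == m, ]
      mcfg <- cfg
      mcfg@energyModel <- mrow$energy
      mcfg@compensationEnabled <- mrow$compensate
      for (r in radii) {
        rr <- r
        if (rr > sp$maxRadius) {
          warning(sprintf(
            "case %d: radius %g clipped to %g (largest circle that fits)",
            ci, rr, floor(sp$maxRadius)))
          rr <- max(2, floor(sp$maxRadius))
        }
        run <- tryCatch(
          runSegmentation(phantomImage(s), sp$center, rr, mcfg, model,
                          classifier_cache = clsCache),
          error = function(e) e)
        if (inherits(run, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            case = ci, method = m, radius = r, dice = NA_real_,
            iterations = NA_integer_, status = "failed")
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            case = ci, method = m, radius = r,
            dice = diceCoefficient(segMask(run), truth),
            iterations = iterations(run), status = run@status)
        }
      }
    }
  }
  rows <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(rows$method), function(m) {
    d <- rows$dice[rows$method == m & !is.na(rows$dice)]
    ciw <- if (length(d) >= 2) ci90(d) else c(mean = mean(d), half_width = NA)
    perCaseSd <- vapply(split(rows$dice[rows$method == m],
                              rows$case[rows$method == m]),
                       function(x) if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE)
                                   else NA_real_, numeric(1))
    data.frame(method = m, n = length(d), mean_dice = unname(ciw[1]),
               sd_dice = sd(d), ci90_half_width = unname(ciw[2]),
               mean_percase_radius_sd = mean(perCaseSd, na.rm = TRUE))
  }))
  list(rows = rows, summary = summ)
}

#' Convergence report for one run
#'
#' @param run a [SegmentationRun].
#' @return list with `trace` (data.frame iteration, energy), `settled_at`
#'   (first iteration after which the energy never again changes by more
#'   than 1% of its final value) and `initial_transient` (whether the energy
#'   rose above its starting value during the first iterations, the
#'   transient bump seen at the start of these evolutions).
#' @export
convergenceReport <- function(run) {
  e <- energyTrace(run)
  n <- length(e)
  if (n == 0) stop("run has no energy trace")
  tol <- 0.01 * max(abs(e[n]), 1e-12)
  settled <- n
  for (i in seq_len(n)) {
    if (all(abs(e[i:n] - e[n]) <= tol)) { settled <- i; break }
  }
  transient <- n >= 3 && max(e[2:min(20, n)]) > e[1] + 1e-9 * abs(e[1])
  list(trace = data.frame(iteration = seq_len(n), energy = e),
       settled_at = settled, initial_transient = transient)
}
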