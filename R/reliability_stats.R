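# Reliability analysis: ICC(2,1) with 95% CI, mean absolute difference,
# and the simulated-examiner study harness.

#' Construct a subjects-by-raters measurement table
#'
#' @param values n_subjects x k_raters numeric matrix of Cobb angles in
#'   degrees; no missing cells, n >= 2, k >= 2.
#' @param subject_ids,rater_ids optional labels.
#' @return object of class `measurement_table`.
#' @export
measurement_table <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("measurement_table needs at least 2 subjects and 2 raters, got ",
         nrow(values), " x ", ncol(values))
  }
  if (anyNA(values)) stop("measurement_table: missing cells are not allowed")
  structure(
    list(values = values,
         subject_ids = subject_ids %||% paste0("S", seq_len(nrow(values))),
         rater_ids = rater_ids %||% paste0("R", seq_len(ncol(values)))),
    class = "measurement_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Computes the single-measurement absolute-agreement ICC — ICC(2,1) in the
#' Shrout-Fleiss taxonomy, ICC(A,1) in McGraw-Wong — from the two-way ANOVA
#' mean squares of a complete subjects-by-raters table, with its 95%
#' confidence interval from the F distribution (Satterthwaite degrees of
#' freedom for the lower/upper bounds).
#'
#' With zero between-subject variance the coefficient is undefined (the
#' variance ratio is 0/0): `icc` is returned as `NA` with a `note`, never as
#' a spurious 0.  With exact perfect agreement (zero rater and residual
#' variance) the interval degenerates to \[1, 1\].
#'
#' @param table a [measurement_table()] or a plain n x k matrix.
#' @param conf_level confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `variant` (`"ICC(2,1)"`),
#'   the ANOVA mean squares, and optionally `note`.
#' @export
icc_absolute_agreement <- function(table, conf_level = 0.95) {
  if (inherits(table, "measurement_table")) table <- table$values
  x <- as.matrix(table)
  if (nrow(x) < 2 || ncol(x) < 2 || anyNA(x)) {
    stop("icc_absolute_agreement needs a complete table with >= 2 rows and columns")
  }
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  scale2 <- mean(x^2) + 1  # reference scale for degeneracy tests
  if (MSR / scale2 < 1e-12) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                variant = "ICC(2,1)", MSR = MSR, MSC = MSC, MSE = MSE,
                note = "undefined: zero between-subject variance"))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  if ((MSE + MSC) / scale2 < 1e-12) {
    # exact perfect agreement: no sampling variability left to bound
    return(list(icc = icc, ci_low = icc, ci_high = icc,
                variant = "ICC(2,1)", MSR = MSR, MSC = MSC, MSE = MSE))
  }

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  lower <- max(-1, min(lower, icc))
  upper <- min(1, max(upper, icc))
  list(icc = icc, ci_low = lower, ci_high = upper,
       variant = "ICC(2,1)", MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Mean absolute difference between paired measurements
#'
#' @param a,b numeric vectors of equal length (>= 1), degrees.
#' @return mean of `|a - b|`, degrees.
#' @export
mean_absolute_difference <- function(a, b) {
  if (length(a) != length(b)) {
    stop("mean_absolute_difference: lengths differ (", length(a), " vs ",
         length(b), ")")
  }
  if (length(a) < 1) stop("mean_absolute_difference: empty input")
  mean(abs(a - b))
}

#' Simulate one examiner measurement session on phantom radiographs
#'
#' Emulates a human examiner whose only source of variability is where they
#' click: every true vertebra centre is perturbed by isotropic Gaussian
#' click noise, the perturbed clicks are fed to [measure()] with the trained
#' network, and one Cobb angle per radiograph is returned.  Perturbed clicks
#' that would push the patch window out of bounds are clamped to the valid
#' margin (count recorded in the `clamped` attribute).
#'
#' @param radiographs list of `phantom_radiograph` objects.
#' @param model trained `dnn_parameters`.
#' @param click_noise_sd standard deviation of the click perturbation in
#'   pixels at the 1000-px standardized height (default 5).
#' @param seed integer; the session is fully determined by it.
#' @return numeric vector of Cobb angles (one per radiograph) with
#'   attribute `clamped` (number of clamped clicks).
#' @export
simulate_examiner_session <- function(radiographs, model, click_noise_sd = 5,
                                      seed = 1L) {
  if (inherits(radiographs, "phantom_radiograph")) radiographs <- list(radiographs)
  clamped <- 0L
  angles <- with_seed(seed, {
    vapply(radiographs, function(rg) {
      v <- rg$truth$vertebrae
      n_v <- nrow(v)
      cx <- v$center_x + stats::rnorm(n_v, 0, click_noise_sd)
      cy <- v$center_y + stats::rnorm(n_v, 0, click_noise_sd)
      W <- ncol(rg$image); H <- nrow(rg$image)
      cx2 <- pmin(pmax(cx, 76), W - 74)
      cy2 <- pmin(pmax(cy, 76), H - 74)
      clamped <<- clamped + sum(cx2 != cx | cy2 != cy)
      rec <- measure(rg$image, cbind(x = cx2, y = cy2), model)
      rec$cobb_angle
    }, numeric(1))
  })
  attr(angles, "clamped") <- clamped
  angles
}

#' Simulated intra-/interobserver reliability study
#'
#' Replicates the design of a repeated-measurement reliability study in
#' silico: several examiner sessions (independent sub-seeds) measure the
#' Cobb angle on the same phantom radiographs; the resulting
#' subjects-by-sessions table is summarized by ICC(2,1) with 95% CI and the
#' mean absolute difference.  An intraobserver design uses the same click
#' noise for every session; an interobserver design may give each session
#' (examiner) its own click-noise level.
#'
#' @param radiographs list of `phantom_radiograph` objects (the subjects).
#' @param model trained `dnn_parameters`.
#' @param design `"intraobserver"` or `"interobserver"` (label recorded in
#'   the report; the variance model is set by `click_noise_sd`).
#' @param sessions number of measurement sessions (>= 2, default 2).
#' @param click_noise_sd scalar, or vector of one sd per session.
#' @param seed integer master seed; sessions get independent sub-seeds.
#' @return object of class `reliability_report`: `icc`, `ci_low`, `ci_high`,
#'   `mad` (mean over session pairs), `variant`, `design`, and the full
#'   measurement `table`.
#' @export
reliability_study <- function(radiographs, model,
                              design = c("intraobserver", "interobserver"),
                              sessions = 2L, click_noise_sd = 5, seed = 1L) {
  design <- match.arg(design)
  if (sessions < 2) stop("reliability_study needs >= 2 sessions")
  sds <- rep_len(click_noise_sd, sessions)
  sub_seeds <- with_seed(seed, sample.int(2147483646L, sessions))
  cols <- lapply(seq_len(sessions), function(s) {
    simulate_examiner_session(radiographs, model, sds[s], sub_seeds[s])
  })
  values <- do.call(cbind, cols)
  tab <- measurement_table(values,
                           rater_ids = paste0("session", seq_len(sessions)))
  icc <- icc_absolute_agreement(tab)
  pairs <- utils::combn(sessions, 2)
  mads <- apply(pairs, 2, function(p) {
    mean_absolute_difference(values[, p[1]], values[, p[2]])
  })
  structure(
    list(icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
         mad = mean(mads), variant = icc$variant, design = design,
         click_noise_sd = sds, table = tab, note = icc$note),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("%s reliability (%s), %d subjects x %d sessions\n",
              x$design, x$variant,
              nrow(x$table$values), ncol(x$table$values)))
  if (is.na(x$icc)) {
    cat("  ICC undefined:", x$note, "\n")
  } else {
    cat(sprintf("  ICC = %.3f (95%% CI %.3f, %.3f), MAD = %.2f deg\n",
                x$icc, x$ci_low, x$ci_high, x$mad))
  }
  invisible(x)
}
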