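# Correlation of biometrics with mode scores over randomly generated
# instances, and the paired comparison of medial vs lateral caudal slope.

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] returning the sample correlation R
#' and the two-sided p from the t distribution with n - 2 df.
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `R`, `p`, `n`.
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearsonCor: undefined correlation (zero variance)")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t-test with difference summary
#'
#' Two-sided paired t on `a - b` via [stats::t.test()], reporting the
#' difference mean and SD. Degenerate constant nonzero differences are
#' reported with `p = 0` and `infiniteT = TRUE`.
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `meanDiff`, `sdDiff`, `n`, `infiniteT`.
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, meanDiff = 0, sdDiff = 0, n = length(d),
                  infiniteT = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, meanDiff = mean(d),
                sdDiff = 0, n = length(d), infiniteT = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, meanDiff = mean(d),
       sdDiff = stats::sd(d), n = length(d), infiniteT = FALSE)
}

#' Mode-score / biometric correlation experiment
#'
#' Draws `nInstances` random score vectors (each mode's SD multiplier
#' independently Uniform(-3, 3) by default, or standard Gaussian), generates
#' the instances, measures every biometric, and correlates each biometric
#' with each mode's score. Mirrors the design of correlating biometrics with
#' modes over 100 randomly generated instances.
#'
#' @param model a [ShapeModel-class] with region labels.
#' @param modes number of leading modes to vary.
#' @param nInstances instances to generate (default 100).
#' @param measurer [measureFemur] or [measureTibia].
#' @param seed integer seed (reproducibility contract: same seed, same
#'   report).
#' @param scoreDist "uniform" (Uniform(-3,3)) or "gaussian" (N(0,1)).
#' @return data.frame with columns biometric, mode, R, p, n plus attributes
#'   `seed`, `scoreDist`, `scores` and `measurements`; failed instances are
#'   dropped and counted in attribute `nFailed`.
#' @export
correlationExperiment <- function(model, modes, nInstances = 100, measurer,
                                  seed = 1,
                                  scoreDist = c("uniform", "gaussian")) {
  scoreDist <- match.arg(scoreDist)
  stopifnot(modes >= 1, modes <= nModes(model))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scores <- matrix(if (scoreDist == "uniform")
    stats::runif(nInstances * modes, -3, 3)
    else stats::rnorm(nInstances * modes), nInstances, modes)
  meas <- NULL
  ok <- logical(nInstances)
  for (i in seq_len(nInstances)) {
    bs <- tryCatch(suppressWarnings(
      measurer(instanceMesh(model, scores[i, ]))), error = function(e) NULL)
    if (is.null(bs)) next
    ok[i] <- TRUE
    meas <- rbind(meas, biometricValues(bs))
  }
  if (sum(ok) < 3) stop("correlationExperiment: fewer than 3 usable instances")
  sc <- scores[ok, , drop = FALSE]
  rows <- NULL
  for (b in colnames(meas)) {
    for (k in seq_len(modes)) {
      pc <- tryCatch(pearsonCor(sc[, k], meas[, b]), error = function(e)
        list(R = NA_real_, p = NA_real_, n = sum(ok)))
      rows <- rbind(rows, data.frame(biometric = b, mode = k, R = pc$R,
                                     p = pc$p, n = pc$n))
    }
  }
  attr(rows, "seed") <- seed
  attr(rows, "scoreDist") <- scoreDist
  attr(rows, "scores") <- sc
  attr(rows, "measurements") <- meas
  attr(rows, "nFailed") <- sum(!ok)
  rows
}
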