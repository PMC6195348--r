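#' Expression volume with lobule masks
#'
#' A per-mouse binary labeled-voxel array (TRUE where reporter label was
#' detected) together with four named, pairwise-disjoint lobule masks of the
#' same shape. Axis order is (anterior-posterior, dorsoventral,
#' mediolateral), on a common isotropic grid (inputs are assumed already
#' registered; the conventional reference grid is 25-micron isotropic).
#'
#' @param label logical (or 0/1) 3-D array of labeled voxels.
#' @param masks named list of four logical arrays (lobule VI, lobule VII,
#'   crus I, crus II), same shape as `label`, pairwise disjoint.
#' @return an object of class `expression_volume`.
#' @export
expression_volume <- function(label, masks) {
  label <- array(as.logical(label), dim(label))
  if (length(dim(label)) != 3L) stop2("label must be a 3-D array")
  if (length(masks) != 4L || is.null(names(masks)))
    stop2("need four named lobule masks")
  masks <- lapply(masks, function(m) array(as.logical(m), dim(m)))
  for (m in masks)
    if (!identical(dim(m), dim(label)))
      stop2("masks must have the same shape as the label array")
  tot <- Reduce(`+`, masks)
  if (any(tot > 1L)) stop2("lobule masks must be pairwise disjoint")
  structure(list(label = label, masks = masks), class = "expression_volume")
}

#' @export
print.expression_volume <- function(x, ...) {
  cat("Expression volume", paste(dim(x$label), collapse = " x "), ":",
      sum(x$label), "labeled voxels\n")
  print(round(lobule_fractions(x), 4L))
  invisible(x)
}

#' Per-lobule expression fractions
#'
#' For each lobule, the fraction of voxels in that lobule in which label was
#' detected: `|label AND mask| / |mask|`.
#'
#' @param v an [expression_volume()].
#' @return named numeric 4-vector of fractions in 0..1.
#' @export
lobule_fractions <- function(v) {
  vapply(v$masks, function(m) {
    denom <- sum(m)
    if (denom == 0L) stop2("empty lobule mask")
    sum(v$label & m) / denom
  }, numeric(1L))
}

#' Classify a mouse by majority lobule
#'
#' The lobule with the largest expression fraction. Ties are broken by the
#' fixed lobule order of the fraction vector and flagged.
#'
#' @param fractions named fraction vector from [lobule_fractions()].
#' @return the lobule name (with attribute `tie = TRUE` when tied), or `NA`
#'   when all fractions are zero (unclassified).
#' @export
classify_majority_lobule <- function(fractions) {
  if (all(fractions == 0)) return(NA_character_)
  top <- which(fractions == max(fractions))
  out <- names(fractions)[top[1L]]
  if (length(top) > 1L) attr(out, "tie") <- TRUE
  out
}

#' Mediolateral expression profile
#'
#' Reduces a labeled volume to a vector over the mediolateral axis:
#' optional voxelwise masking by a region of interest, max-projection along
#' the anterior-posterior axis, then the mean over the dorsoventral axis at
#' each mediolateral coordinate.
#'
#' @param v an [expression_volume()].
#' @param roi optional logical array (same shape) used as a voxelwise
#'   inclusion filter before projection.
#' @return numeric vector of length `dim(label)[3]`.
#' @export
expression_vector <- function(v, roi = NULL) {
  lab <- v$label
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(lab)))
      stop2("roi must have the same shape as the volume")
    lab <- lab & roi
  }
  proj <- apply(lab, c(2L, 3L), max)   # max over anterior-posterior
  colMeans(proj)                       # mean over dorsoventral
}

#' Fit per-metric linear dosage models
#'
#' One ordinary-least-squares model per behavioral metric, relating the
#' metric value of each injected mouse to the fraction of each of the four
#' targeted lobules containing label, plus an intercept. Only injected
#' (experimental) mice enter: uninjected controls have no expression and are
#' excluded by construction. The three discrete Y-maze metrics
#' (final learning, initial reversal 2, final reversal 2) are excluded by
#' default; models are meant for continuous-valued metrics. Fit one model
#' set per cohort (juvenile-perturbed and adult-perturbed separately).
#'
#' @param metrics a [metric_matrix()] of the injected cohort.
#' @param fractions n x 4 matrix of lobule expression fractions (rows
#'   aligned with the metric matrix's mice; columns named by lobule).
#' @param exclude metric names not modeled.
#' @param min_n minimum number of mice with a non-missing metric value.
#' @return an object of class `dosage_fit`: a named list with one element
#'   per modeled metric, each a data frame `term, estimate, se, normalized`
#'   (normalized = estimate / se), plus attribute `n` per metric.
#' @export
fit_dosage_models <- function(metrics, fractions,
                              exclude = c("YM_Final Learning",
                                          "YM_Initial Reversal 2",
                                          "YM_Final Reversal 2"),
                              min_n = 6L) {
  mm <- attr(metrics, "metrics") %||%
    setdiff(names(metrics), c("mouse", "group"))
  mm <- setdiff(mm, exclude)
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != nrow(metrics))
    stop2("fractions must have one row per mouse")
  if (ncol(fractions) != 4L) stop2("fractions must have four lobule columns")
  lobules <- colnames(fractions) %||% paste0("lobule", 1:4)
  X <- cbind(`(Intercept)` = 1, fractions)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop2("rank-deficient design: collinear lobule column(s) ",
          paste(setdiff(dropped, "(Intercept)"), collapse = ", "))
  }
  fits <- list(); ns <- integer(0)
  for (met in mm) {
    y <- as.numeric(metrics[[met]])
    ok <- !is.na(y)
    if (sum(ok) < min_n) next
    df <- data.frame(y = y[ok], fractions[ok, , drop = FALSE],
                     check.names = FALSE)
    fit <- lm(stats::reformulate(sprintf("`%s`", lobules), "y"), data = df)
    sm <- suppressWarnings(summary(fit))$coefficients
    fits[[met]] <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                              se = sm[, 2L], normalized = sm[, 1L] / sm[, 2L],
                              row.names = NULL, stringsAsFactors = FALSE)
    ns[met] <- sum(ok)
  }
  structure(fits, n = ns, class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat("Dosage models for", length(x), "metric(s)\n")
  for (met in names(x)) {
    cat("\n", met, " (n = ", attr(x, "n")[met], ")\n", sep = "")
    print(transform(x[[met]], estimate = signif(estimate, 4L),
                    se = signif(se, 4L), normalized = round(normalized, 2L)))
  }
  invisible(x)
}

#' Relative neocortical expression from tracing section counts
#'
#' Divides each region's GFP-positive section count by the motor-cortex
#' count (motor cortex, always labeled, is the reference and maps to 1).
#'
#' @param counts named numeric vector of per-region section counts (>= 0);
#'   must include the reference region with a positive count.
#' @param reference name of the reference region.
#' @return named vector of relative expression ratios.
#' @export
relative_expression <- function(counts, reference = "motor") {
  if (any(counts < 0)) stop2("section counts must be non-negative")
  if (!reference %in% names(counts))
    stop2("reference region '", reference, "' not in counts")
  if (counts[[reference]] <= 0)
    stop2("reference region count must be positive")
  counts / counts[[reference]]
}

#' Write / read an expression volume as plain text
#'
#' The directory receives a JSON manifest (`manifest.json` with dimensions
#' and mask names) plus one 0/1 text file per array (label and each mask),
#' voxel values in column-major order.
#'
#' @param v an [expression_volume()].
#' @param dir output directory (created if needed).
#' @return `write_expression_volume` returns `dir` invisibly;
#'   `read_expression_volume` returns the [expression_volume()].
#' @export
write_expression_volume <- function(v, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(dim = dim(v$label), masks = names(v$masks)),
                       file.path(dir, "manifest.json"), auto_unbox = FALSE)
  writeLines(paste(as.integer(v$label), collapse = ""),
             file.path(dir, "label.txt"))
  for (nm in names(v$masks))
    writeLines(paste(as.integer(v$masks[[nm]]), collapse = ""),
               file.path(dir, paste0("mask_", nm, ".txt")))
  invisible(dir)
}

#' @rdname write_expression_volume
#' @export
read_expression_volume <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  read_arr <- function(path) {
    bits <- strsplit(readLines(path, n = 1L), "")[[1L]]
    array(bits == "1", man$dim)
  }
  masks <- lapply(man$masks, function(nm)
    read_arr(file.path(dir, paste0("mask_", nm, ".txt"))))
  names(masks) <- man$masks
  expression_volume(read_arr(file.path(dir, "label.txt")), masks)
}
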