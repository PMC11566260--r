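#' Median and inclusive-interpolation quartiles
#'
#' Quartiles use linear interpolation between order statistics (R's default
#' type-7 / "inclusive" method) - the method matters for IQR-style
#' reporting, so it is fixed and documented.
#'
#' @param values numeric vector with at least one finite value.
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the signed-rank convention) before testing;
#' the exact null distribution is used for n <= 25 remaining pairs, the
#' normal approximation with continuity correction above that. All-zero
#' differences give an undefined p-value (`NA` with a message) rather than a
#' number.
#'
#' @param x,y equal-length paired observations (>= 5 non-zero differences).
#' @return list with `p_value`, `n_used` (pairs after dropping zeros) and
#'   `n_zero_dropped`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- y - x
  keep <- d != 0
  n <- sum(keep)
  n_zero <- sum(!keep)
  if (n == 0L)
    return(list(p_value = NA_real_, n_used = 0L, n_zero_dropped = n_zero))
  if (n < 5L) stop("fewer than 5 non-zero paired differences (n = ", n, ")")
  ht <- suppressWarnings(stats::wilcox.test(
    x[keep], y[keep], paired = TRUE, alternative = "two.sided",
    exact = n <= 25L, correct = TRUE))
  list(p_value = ht$p.value, n_used = n, n_zero_dropped = n_zero)
}

read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    base <- dirname(normalizePath(manifest))
    df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    for (col in c("image_a", "image_b", "mask", "control_points", "lines")) {
      abs <- file.path(base, df[[col]])
      df[[col]] <- ifelse(file.exists(df[[col]]), df[[col]], abs)
    }
    df
  } else {
    as.data.frame(manifest, stringsAsFactors = FALSE)
  }
}

process_slice <- function(entry, config) {
  pitch <- entry$pixel_pitch
  a <- read_image_tiff(entry$image_a, pixel_pitch = pitch, modality = "A")
  b <- read_image_tiff(entry$image_b, pixel_pitch = pitch, modality = "B")
  mask <- read_mask_png(entry$mask)
  cps <- utils::read.csv(entry$control_points)
  T_reg <- fit_similarity(moving = as.matrix(cps[, c("moving_row", "moving_col")]),
                          fixed = as.matrix(cps[, c("fixed_row", "fixed_col")]))
  b_reg <- apply_transform(b, T_reg, output_shape = dim(a),
                           interpolation = "bilinear")
  bg_mask <- !mask

  slice_row <- function(img, modality) {
    ts <- roi_stats(img, mask)
    bs <- roi_stats(img, bg_mask)
    data.frame(slice_id = entry$slice_id, modality = modality,
               tbr = tbr(ts, bs), acnr = acnr(ts, bs),
               tumor_mfi = ts$mfi, tumor_sd = ts$sd, tumor_n = ts$n,
               bg_mfi = bs$mfi, bg_sd = bs$sd, bg_n = bs$n,
               stringsAsFactors = FALSE)
  }
  slices <- rbind(slice_row(a, "A"), slice_row(b_reg, "B"))

  ldf <- utils::read.csv(entry$lines)
  line_rows <- list()
  for (j in seq_len(nrow(ldf))) {
    ls <- line_spec(c(ldf$start_row[j], ldf$start_col[j]),
                    c(ldf$end_row[j], ldf$end_col[j]),
                    width = config$line_width, pixel_pitch = pitch)
    for (mod in c("A", "B")) {
      img <- if (mod == "A") a else b_reg
      res <- tryCatch(
        analyze_line(img, ls, mask, sigma_perp = config$collapse_sigma(ls),
                     scope = config$line_mean_scope),
        error = function(e) e)
      if (inherits(res, "error")) {
        line_rows[[length(line_rows) + 1L]] <- data.frame(
          slice_id = entry$slice_id, line_id = ldf$line_id[j], modality = mod,
          mean_tbr = NA_real_, mean_acnr = NA_real_, auc_acnr = NA_real_,
          crossing_position = NA_real_, crossing_distance = NA_real_,
          border_position = NA_real_, failure = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        line_rows[[length(line_rows) + 1L]] <- data.frame(
          slice_id = entry$slice_id, line_id = ldf$line_id[j], modality = mod,
          mean_tbr = res$mean_tbr, mean_acnr = res$mean_acnr,
          auc_acnr = res$auc_acnr,
          crossing_position = res$crossing_position,
          crossing_distance = res$crossing_distance,
          border_position = res$profile$border_position, failure = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  lines <- do.call(rbind, line_rows)

  pp <- collect_paired_pixels(a, b_reg, mask, bg_mask)
  ba <- bland_altman(pp$a, pp$b)
  pixels <- data.frame(
    slice_id = entry$slice_id,
    r_squared = linear_r2(pp$a, pp$b),
    bias = ba$bias, bias_sd = ba$sd,
    overlap_pct_a = tumor_bg_overlap(pp, "a"),
    overlap_pct_b = tumor_bg_overlap(pp, "b"),
    n_pairs = nrow(pp), stringsAsFactors = FALSE)

  list(slices = slices, lines = lines, pixels = pixels,
       registration = T_reg)
}

#' Run a two-modality comparison study
#'
#' Executes the full pipeline over a manifest of slices: register modality B
#' onto modality A through the slice's control points, compute whole-slice
#' TBR and aCNR per modality, run the line-based border analysis for every
#' annotated line, collect pixel-level agreement statistics, and aggregate
#' everything into a median (IQR) comparison table with paired Wilcoxon
#' p-values. Deterministic given the manifest and configuration. A slice
#' that fails is skipped with its reason recorded; a study in which every
#' slice fails is an error.
#'
#' @param manifest path to a `manifest.csv` (columns `slice_id`, `image_a`,
#'   `image_b`, `mask`, `control_points`, `lines`, `pixel_pitch`; relative
#'   paths are resolved against the manifest's directory) or an equivalent
#'   data.frame with resolvable paths.
#' @param config optional overrides: `line_width` (default 11),
#'   `collapse_sigma` (default `width / 6`), `line_mean_scope`
#'   (`"all"` or `"tumor"`).
#' @param out_dir optional directory; when given, per-slice, per-line and
#'   comparison CSVs are written there.
#' @return list with `slices`, `lines`, `pixels` (per-unit data.frames),
#'   `comparison` (the study-level table), `agreement` (aCNR = 1 crossing
#'   agreement of B against A as reference) and `failures`.
#' @export
run_study <- function(manifest, config = list(), out_dir = NULL) {
  cfg <- list(line_width = 11L,
              collapse_sigma = function(ls) ls$width / 6,
              line_mean_scope = "all")
  cfg[names(config)] <- config
  if (!is.function(cfg$collapse_sigma)) {
    sig <- cfg$collapse_sigma
    cfg$collapse_sigma <- function(ls) sig
  }
  mf <- read_manifest(manifest)
  results <- list(); failures <- list()
  for (k in seq_len(nrow(mf))) {
    res <- tryCatch(process_slice(mf[k, ], cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[mf$slice_id[k]]] <- conditionMessage(res)
    } else {
      results[[mf$slice_id[k]]] <- res
    }
  }
  if (length(results) == 0L)
    stop("every slice failed; first reason: ", failures[[1]])
  slices <- do.call(rbind, lapply(results, `[[`, "slices"))
  lines <- do.call(rbind, lapply(results, `[[`, "lines"))
  pixels <- do.call(rbind, lapply(results, `[[`, "pixels"))
  rownames(slices) <- rownames(lines) <- rownames(pixels) <- NULL

  comparison <- build_comparison(slices, lines)

  la <- lines[lines$modality == "A", ]
  lb <- lines[lines$modality == "B", ]
  agreement <- crossing_agreement(test_found = !is.na(lb$crossing_position),
                                  reference_found = !is.na(la$crossing_position))

  out <- list(slices = slices, lines = lines, pixels = pixels,
              comparison = comparison, agreement = agreement,
              failures = failures)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(slices, file.path(out_dir, "per_slice.csv"), row.names = FALSE)
    utils::write.csv(lines, file.path(out_dir, "per_line.csv"), row.names = FALSE)
    utils::write.csv(pixels, file.path(out_dir, "pixel_agreement.csv"), row.names = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  out
}

# Paired A-vs-B summary (median, IQR, Wilcoxon) per metric. Pairs with a
# missing value in either modality are dropped; n reports pairs used.
build_comparison <- function(slices, lines) {
  paired <- function(df, metric, key) {
    w <- stats::reshape(df[, c(key, "modality", metric)],
                        idvar = key, timevar = "modality", direction = "wide")
    a <- w[[paste0(metric, ".A")]]; b <- w[[paste0(metric, ".B")]]
    ok <- is.finite(a) & is.finite(b)
    list(a = a[ok], b = b[ok])
  }
  lines$pair_id <- paste(lines$slice_id, lines$line_id, sep = ":")
  specs <- list(
    list(metric = "tbr", df = slices, key = "slice_id", label = "TBR whole tissue slice"),
    list(metric = "acnr", df = slices, key = "slice_id", label = "aCNR whole tissue slice"),
    list(metric = "mean_tbr", df = lines, key = "pair_id", label = "TBR over line"),
    list(metric = "mean_acnr", df = lines, key = "pair_id", label = "aCNR over line"),
    list(metric = "auc_acnr", df = lines, key = "pair_id", label = "AUC aCNR"),
    list(metric = "crossing_distance", df = lines, key = "pair_id",
         label = "Absolute distance tumor border to aCNR=1 (mm)"))
  rows <- lapply(specs, function(s) {
    p <- paired(s$df, s$metric, s$key)
    n <- length(p$a)
    if (n == 0L) {
      return(data.frame(metric = s$label, n = 0L,
                        median_a = NA_real_, q1_a = NA_real_, q3_a = NA_real_,
                        median_b = NA_real_, q1_b = NA_real_, q3_b = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ma <- median_iqr(p$a); mb <- median_iqr(p$b)
    pv <- tryCatch(paired_wilcoxon(p$a, p$b)$p_value, error = function(e) NA_real_)
    data.frame(metric = s$label, n = n,
               median_a = ma["median"], q1_a = ma["q1"], q3_a = ma["q3"],
               median_b = mb["median"], q1_b = mb["q1"], q3_b = mb["q3"],
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
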