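#' Histologic category vocabulary (9 classes at 10x)
#' @return character vector: six tumor subtypes, leukocyte aggregates,
#'   necrosis, other
#' @export
histology_categories <- function() {
  c("acinar", "cribriform", "lepidic", "micropapillary", "papillary", "solid",
    "leukocyte_aggregates", "necrosis", "other")
}

tumor_subtypes <- function() histology_categories()[1:6]

#' Build a label map from an integer/character raster
#' @param raster matrix of category names or 1-based indices into
#'   `categories`
#' @param categories category vocabulary
#' @return integer matrix with a `"categories"` attribute
#' @export
label_map <- function(raster, categories = histology_categories()) {
  if (is.character(raster[1])) {
    idx <- match(raster, categories)
    if (anyNA(idx)) vs_abort("unknown label in raster")
    m <- matrix(idx, nrow(raster), ncol(raster))
  } else {
    m <- matrix(as.integer(raster), nrow(raster), ncol(raster))
    if (any(m < 1 | m > length(categories))) vs_abort("label index outside the vocabulary")
  }
  attr(m, "categories") <- categories
  class(m) <- c("label_map", class(m))
  m
}

#' Dice overlap between two boolean masks
#'
#' `2 |a & b| / (|a| + |b|)`. Two empty masks are defined as perfectly
#' concordant (Dice 1, logged); empty vs nonempty gives 0.
#'
#' @param a,b logical matrices of equal shape
#' @return Dice coefficient in \[0, 1\]
#' @export
dice_score <- function(a, b) {
  if (!all(dim(a) == dim(b))) vs_abort("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    rlang::inform("both masks empty: Dice defined as 1")
    return(1.0)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Merge the six tumor subtypes into a single combined-tumor category
#'
#' Used for any analysis involving non-LUAD cases, where per-subtype labels
#' are not applicable. Pixel counts are conserved: the combined-tumor count
#' equals the sum of the subtype counts.
#'
#' @param map a [label_map()] over the 9-class vocabulary
#' @return a 4-class [label_map()] (combined_tumor, leukocyte_aggregates,
#'   necrosis, other)
#' @export
merge_combined_tumor <- function(map) {
  stopifnot(inherits(map, "label_map"))
  cats <- attr(map, "categories")
  if (!all(cats == histology_categories())) vs_abort("unknown label vocabulary")
  new_cats <- c("combined_tumor", "leukocyte_aggregates", "necrosis", "other")
  remap <- c(rep(1L, 6L), 2L, 3L, 4L)
  out <- matrix(remap[as.integer(map)], nrow(map), ncol(map))
  label_map(out, new_cats)
}

#' Per-category Dice between two label maps
#' @param real,virtual [label_map()]s with identical vocabularies
#' @return tibble (category, dice)
#' @export
dice_by_category <- function(real, virtual) {
  cats <- attr(real, "categories")
  if (!identical(cats, attr(virtual, "categories"))) vs_abort("label vocabularies differ")
  purrr::map_dfr(seq_along(cats), function(i) {
    tibble::tibble(category = cats[i],
                   dice = suppressMessages(dice_score(unclass(real) == i,
                                                      unclass(virtual) == i)))
  })
}

#' Filter cases by minimum subtype prevalence (the 5% rule)
#'
#' Retains cases in which the subtype's area strictly exceeds 5% of that
#' case's total tumor area. Cases with zero total tumor area are excluded
#' with a warning.
#'
#' @param cases tibble with columns `case`, `subtype`, `area` (long format:
#'   one row per case x subtype)
#' @param subtype the subtype being analysed
#' @param min_fraction prevalence threshold (strict), default 0.05
#' @return the retained subset of case ids
#' @export
luad5_subset <- function(cases, subtype, min_fraction = 0.05) {
  stopifnot(all(c("case", "subtype", "area") %in% names(cases)))
  if (!subtype %in% tumor_subtypes()) vs_abort(sprintf("'%s' is not a tumor subtype", subtype))
  tot <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cases, .data$subtype %in% tumor_subtypes()),
                    .data$case),
    total = sum(.data$area), .groups = "drop")
  zero <- tot$case[tot$total == 0]
  if (length(zero)) {
    rlang::warn(sprintf("%d case(s) with zero tumor area excluded", length(zero)))
  }
  sub <- dplyr::filter(cases, .data$subtype == !!subtype)
  j <- dplyr::inner_join(sub, dplyr::filter(tot, .data$total > 0), by = "case")
  j$case[j$area / j$total > min_fraction]
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson r with the standard normal-approximation CI on the
#' Fisher-transformed scale, `atanh(r) +/- z_{1-alpha/2} / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors, n >= 4, finite
#' @param alpha two-sided error rate (default 0.05 for a 95% CI)
#' @return tibble (r, ci_low, ci_high, n)
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 4) vs_abort("need paired vectors of length >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) vs_abort("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) vs_abort("undefined correlation: zero variance")
  r <- cor(x, y)
  # exactly (anti)correlated up to floating roundoff: degenerate CI
  if (abs(r) >= 1 - 1e-12) {
    r <- sign(r)
    return(tibble::tibble(r = r, ci_low = r, ci_high = r, n = length(x)))
  }
  z <- atanh(r)
  se <- 1 / sqrt(length(x) - 3)
  q <- qnorm(1 - alpha / 2)
  tibble::tibble(r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
                 n = length(x))
}

#' Real-vs-virtual concordance summary over paired measurement sets
#'
#' Joins real and virtual measurements by case, ROI, measure and marker,
#' then reports per (roi, measure, marker): Pearson r with 95% CI, the mean
#' absolute difference, the number of complete pairs, and the number of
#' pairs dropped because either side was undefined (e.g. TPS with no tumor
#' cells). Invariant to case ordering.
#'
#' @param real,virtual tibbles of stacked [measure_roi()] outputs with a
#'   `case` column
#' @param alpha CI error rate
#' @return a `concordance_report` tibble
#' @export
paired_summary <- function(real, virtual, alpha = 0.05) {
  need <- c("case", "roi", "measure", "marker", "value")
  stopifnot(all(need %in% names(real)), all(need %in% names(virtual)))
  j <- dplyr::inner_join(
    dplyr::select(real, dplyr::all_of(need)),
    dplyr::select(virtual, dplyr::all_of(need)),
    by = c("case", "roi", "measure", "marker"), suffix = c("_real", "_virtual"))
  if (nrow(j) == 0) vs_abort("no complete real/virtual pairs")
  out <- dplyr::group_modify(
    dplyr::group_by(j, .data$roi, .data$measure, .data$marker),
    function(d, key) {
      ok <- is.finite(d$value_real) & is.finite(d$value_virtual)
      dropped <- sum(!ok)
      d <- d[ok, ]
      if (nrow(d) == 0) {
        return(tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                              mean_abs_diff = NA_real_, n_pairs = 0L,
                              n_dropped = dropped))
      }
      ci <- tryCatch(pearson_ci(d$value_real, d$value_virtual, alpha),
                     error = function(e) tibble::tibble(r = NA_real_,
                                                        ci_low = NA_real_,
                                                        ci_high = NA_real_,
                                                        n = nrow(d)))
      tibble::tibble(r = ci$r, ci_low = ci$ci_low, ci_high = ci$ci_high,
                     mean_abs_diff = mean(abs(d$value_real - d$value_virtual)),
                     n_pairs = nrow(d), n_dropped = dropped)
    })
  out <- dplyr::ungroup(out)
  class(out) <- c("concordance_report", class(out))
  out
}

#' Summarize per-case Dice scores as mean, SD and median
#' @param dice_tbl tibble with columns `case`, `category`, `dice`
#' @return tibble (category, dice_mean, dice_sd, dice_median, n_cases)
#' @export
dice_summary <- function(dice_tbl) {
  dplyr::ungroup(dplyr::summarise(
    dplyr::group_by(dice_tbl, .data$category),
    dice_mean = mean(.data$dice), dice_sd = sd(.data$dice),
    dice_median = median(.data$dice), n_cases = dplyr::n(),
    .groups = "drop"))
}
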