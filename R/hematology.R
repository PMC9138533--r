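# Complete-blood-count and cytokine table ingestion and derived ratios.

#' Derive blood-count ratios
#'
#' Computes, per subject, the neutrophil-to-lymphocyte ratio
#' (`NLR = Neu / Lym`), the lymphocyte-to-monocyte ratio (`LMR`), the
#' platelet-to-lymphocyte ratio (`PLR`) and the percentage-based
#' `NLR_pct = Neu_pct / Lym_pct`. Zero or missing denominators yield `NA`
#' with a warning (flagged missing, never a silent zero). Ratios computed
#' from columns absent in the input are omitted.
#'
#' Note that the cohort *average* of a ratio is a mean of per-subject
#' ratios; it does not equal the ratio of cohort-average counts (1.823 /
#' 2.994 = 0.609 while the published cohort-average NLR is 0.618).
#'
#' @param panel Data frame with (a subset of) columns `Neu`, `Lym`, `Mon`,
#'   `PLT`, `Neu_pct`, `Lym_pct` in the printed units.
#' @return Data frame of the derivable ratios, one row per input row.
#' @export
derive_ratios <- function(panel) {
  assert_that(is.data.frame(panel), "panel must be a data frame")
  ratio <- function(num, den, name) {
    if (!all(c(num, den) %in% names(panel))) return(NULL)
    d <- panel[[den]]
    bad <- !is.na(d) & d == 0
    if (any(bad)) {
      warning(sprintf("%s: %d subject(s) with zero %s; ratio set to NA",
                      name, sum(bad), den), call. = FALSE)
      d[bad] <- NA_real_
    }
    panel[[num]] / d
  }
  out <- list(NLR = ratio("Neu", "Lym", "NLR"),
              LMR = ratio("Lym", "Mon", "LMR"),
              PLR = ratio("PLT", "Lym", "PLR"),
              NLR_pct = ratio("Neu_pct", "Lym_pct", "NLR_pct"))
  out <- out[!vapply(out, is.null, logical(1))]
  assert_that(length(out) > 0, "no ratio-forming column pairs present")
  as.data.frame(out)
}

# sanity bounds: published cohort min-max widened by 50% each way.
panel_sanity_bounds <- function() {
  b <- rbind(cbc_ranges(), cytokine_ranges())
  half <- (b$max - b$min) / 2
  mid <- (b$max + b$min) / 2
  data.frame(name = b$name, lo = mid - 1.5 * half, hi = mid + 1.5 * half,
             stringsAsFactors = FALSE)
}

#' Read a cohort table from CSV
#'
#' Requires `subject_id`, `cd45` and the full CBC and cytokine panels;
#' unknown columns are preserved as extra features. Values outside the
#' published cohort ranges widened by 50% trigger warnings (never errors);
#' non-numeric cells in numeric columns and missing required columns are
#' errors.
#'
#' @param path CSV file path.
#' @param check_bounds Apply the range sanity warnings (default TRUE).
#' @return Data frame, one row per subject.
#' @export
read_cohort_csv <- function(path, check_bounds = TRUE) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "cd45", cbc_ranges()$name, cytokine_ranges()$name)
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0,
              paste0("cohort CSV is missing required column(s): ",
                     paste(missing, collapse = ", ")))
  for (col in setdiff(required, "subject_id")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      assert_that(!anyNA(vn[!is.na(v) & v != ""]),
                  paste0("non-numeric value in column ", col))
      df[[col]] <- vn
    }
  }
  if (check_bounds) {
    sb <- panel_sanity_bounds()
    for (r in seq_len(nrow(sb))) {
      col <- sb$name[r]
      if (!col %in% names(df)) next
      v <- df[[col]]
      out <- which(!is.na(v) & (v < sb$lo[r] | v > sb$hi[r]))
      if (length(out))
        warning(sprintf("%s: %d value(s) outside the expected range [%.4g, %.4g]",
                        col, length(out), sb$lo[r], sb$hi[r]), call. = FALSE)
    }
  }
  df
}
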