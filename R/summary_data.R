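CANONICAL_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                    "beta", "se", "pval", "n", "n_case", "n_control")
MANDATORY_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
BASES <- c("A", "C", "G", "T")

#' Construct a validated GWAS summary-statistics table
#'
#' A `gwas_table` is a data frame with one row per SNP and canonical columns
#' `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#' (plus optional `n_case`/`n_control` for binary traits), carrying trait
#' metadata as attributes. For binary traits `beta` is on the log odds-ratio
#' scale. Rows violating the type invariants (non-ACGT or identical alleles,
#' non-positive SE, `eaf` outside `[0, 1]`, p-value outside `(0, 1]`,
#' non-finite beta) are dropped with a logged count; a p-value of exactly 0 is
#' floored to `1e-300` with a warning. `eaf` and `n` may be missing (`NA`).
#'
#' @param x data frame holding at least the mandatory canonical columns.
#' @param trait_name trait label.
#' @param trait_units unit string (e.g. `"year"`, `"log(OR)"`).
#' @param is_binary logical; `TRUE` marks a binary trait (log-OR betas).
#' @param sex `"female"` or `"both"`.
#' @param n default per-SNP sample size used where the `n` column is absent.
#' @return A `gwas_table` (data frame subclass) with attributes `trait_name`,
#'   `trait_units`, `is_binary`, `sex` and `n_dropped`.
#' @export
gwas_table <- function(x, trait_name = "trait", trait_units = "unit",
                       is_binary = FALSE, sex = c("both", "female"), n = NA_real_) {
  sex <- match.arg(sex)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANDATORY_COLS, names(x))
  if (length(missing_cols)) {
    stop_mr("mr_format_error", "missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(CANONICAL_COLS, names(x))) x[[col]] <- NA_real_
  x <- x[CANONICAL_COLS]
  x$snp <- as.character(x$snp)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  if (all(is.na(x$n))) x$n <- n

  zero_p <- !is.na(x$pval) & x$pval == 0
  if (any(zero_p)) {
    warning(sprintf("%d p-value(s) of exactly 0 floored to 1e-300", sum(zero_p)))
    x$pval[zero_p] <- 1e-300
  }

  ok <- !is.na(x$snp) & nzchar(x$snp) &
    x$effect_allele %in% BASES & x$other_allele %in% BASES &
    x$effect_allele != x$other_allele &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$pval) & x$pval > 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    mr_log("INFO", "gwas_table(%s): dropped %d invalid row(s)", trait_name, n_dropped)
  }
  x <- x[ok, , drop = FALSE]
  if (anyDuplicated(x$snp)) {
    stop_mr("mr_format_error", "duplicate snp ids in table '%s'", trait_name)
  }
  if (nrow(x) == 0) {
    stop_mr("mr_empty_error", "no valid rows in table '%s' after validation", trait_name)
  }
  rownames(x) <- NULL
  structure(x,
            trait_name = trait_name, trait_units = trait_units,
            is_binary = isTRUE(is_binary), sex = sex, n_dropped = n_dropped,
            class = c("gwas_table", "data.frame"))
}

trait_name <- function(g) attr(g, "trait_name") %||% "trait"
is_binary_trait <- function(g) isTRUE(attr(g, "is_binary"))

# subset rows of a gwas_table preserving metadata attributes
gwas_subset <- function(g, idx) {
  out <- as.data.frame(g)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_name", "trait_units", "is_binary", "sex", "n_dropped")) {
    attr(out, a) <- attr(g, a)
  }
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s (%s), %s trait, %d SNPs\n",
              trait_name(x), attr(x, "trait_units") %||% "unit",
              if (is_binary_trait(x)) "binary" else "continuous", nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read GWAS summary statistics from a TSV file
#'
#' Reads a tab-separated file with a header row into a validated
#' [gwas_table()]. `column_map` translates arbitrary source headers to the
#' canonical names, e.g. `c(snp = "rsid", beta = "effect")` maps the file's
#' `rsid` column to `snp`.
#'
#' @param path file path.
#' @param column_map named character vector `canonical = source`; `NULL` if the
#'   file already uses canonical names.
#' @inheritParams gwas_table
#' @return a validated `gwas_table`.
#' @export
read_gwas <- function(path, column_map = NULL, trait_name = NULL,
                      trait_units = "unit", is_binary = FALSE,
                      sex = "both", n = NA_real_) {
  if (!file.exists(path)) stop_mr("mr_io_error", "file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop_mr("mr_format_error",
                "column '%s' (mapped to '%s') not found in %s", src, canon, path)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_cols)) {
    stop_mr("mr_format_error", "file %s lacks mandatory column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  }
  gwas_table(raw,
             trait_name = trait_name %||% basename(path),
             trait_units = trait_units, is_binary = is_binary,
             sex = sex, n = n)
}

#' Write a GWAS table to TSV
#'
#' Writes canonical columns with full double precision so that
#' `read_gwas(write_gwas(g))` round-trips to better than 1e-12.
#'
#' @param g a `gwas_table`.
#' @param path output path.
#' @export
write_gwas <- function(g, path) {
  stopifnot(inherits(g, "gwas_table"))
  write_tsv_full(as.data.frame(g), path)
}

# full-precision TSV writer shared by all serializers
write_tsv_full <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_mr("mr_io_error", "cannot write %s: %s", path,
                           conditionMessage(ok))
  invisible(path)
}

#' Construct a sparse pairwise LD (r-squared) lookup
#'
#' Stores r-squared for unordered SNP pairs; absent pairs default to 0 and
#' the diagonal is 1 by definition.
#'
#' @param snp_a,snp_b character vectors of SNP ids.
#' @param r2 numeric vector of r-squared values in `[0, 1]`.
#' @return an `ld_matrix` object queried with [ld_r2()].
#' @export
ld_matrix <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  if (length(r2) && (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))) {
    stop_mr("mr_validation_error", "r2 values must lie in [0, 1]")
  }
  key <- pair_key(snp_a, snp_b)
  if (anyDuplicated(key)) {
    agg <- tapply(r2, key, function(v) diff(range(v)))
    if (any(agg > 1e-9)) {
      stop_mr("mr_validation_error",
              "duplicate LD pair(s) disagree by more than 1e-9")
    }
    keep <- !duplicated(key)
    key <- key[keep]; r2 <- r2[keep]
  }
  entries <- as.numeric(r2)
  names(entries) <- key
  structure(list(entries = entries), class = "ld_matrix")
}

pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

#' Query pairwise r-squared
#'
#' @param ld an `ld_matrix`.
#' @param snp_a,snp_b SNP id vectors (recycled to common length).
#' @return numeric vector of r-squared; 1 on the diagonal, 0 for absent pairs.
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  stopifnot(inherits(ld, "ld_matrix"))
  n <- max(length(snp_a), length(snp_b))
  snp_a <- rep_len(as.character(snp_a), n)
  snp_b <- rep_len(as.character(snp_b), n)
  out <- unname(ld$entries[pair_key(snp_a, snp_b)])
  out[is.na(out)] <- 0
  out[snp_a == snp_b] <- 1
  out
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d stored pair(s)\n", length(x$entries)))
  invisible(x)
}

#' Read a long-format LD table
#'
#' Expects a TSV with columns `snp_a`, `snp_b`, `r2`. Duplicate pairs must
#' agree within 1e-9; values outside `[0, 1]` are rejected.
#'
#' @param path file path.
#' @return an `ld_matrix`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop_mr("mr_io_error", "file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_mr("mr_format_error", "LD file lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  ld_matrix(raw$snp_a, raw$snp_b, as.numeric(raw$r2))
}

#' Write an LD table to long-format TSV
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  key <- names(ld$entries)
  parts <- strsplit(key, "\r", fixed = TRUE)
  df <- data.frame(snp_a = vapply(parts, `[`, "", 1),
                   snp_b = vapply(parts, `[`, "", 2),
                   r2 = unname(ld$entries), stringsAsFactors = FALSE)
  write_tsv_full(df, path)
}

RESULT_COLS <- c("exposure", "outcome", "method", "n_snp", "estimate", "se",
                 "or", "ci_low", "ci_high", "pval", "adjusted_for")

#' Serialize MR results to TSV
#'
#' One row per result with columns `exposure`, `outcome`, `method`, `n_snp`,
#' `estimate`, `se`, `or`, `ci_low`, `ci_high`, `pval`, `adjusted_for`
#' (odds-ratio fields are `NA` for continuous outcomes). Values round-trip
#' through [read_results()] to better than 1e-12.
#'
#' @param results a non-empty list of `mr_result` objects (or a data frame
#'   already in result layout).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  df <- results_to_df(results)
  if (nrow(df) == 0) stop_mr("mr_empty_error", "no results to write")
  write_tsv_full(df, path)
}

results_to_df <- function(results) {
  if (is.data.frame(results)) {
    missing_cols <- setdiff(RESULT_COLS, names(results))
    if (length(missing_cols)) {
      stop_mr("mr_format_error", "result frame lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
    }
    return(results[RESULT_COLS])
  }
  if (inherits(results, "mr_result")) results <- list(results)
  if (length(results) == 0) stop_mr("mr_empty_error", "no results to write")
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "mr_result"))
    data.frame(exposure = r$exposure %||% NA_character_,
               outcome = r$outcome %||% NA_character_,
               method = r$method, n_snp = r$n_snp,
               estimate = r$estimate, se = r$se,
               or = r$or %||% NA_real_,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               adjusted_for = r$adjusted_for %||% "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read back a results TSV written by [write_results()]
#' @param path file path.
#' @return data frame with the 11 canonical result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_mr("mr_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESULT_COLS, names(df))
  if (length(missing_cols)) {
    stop_mr("mr_format_error", "results file lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  df[RESULT_COLS]
}
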