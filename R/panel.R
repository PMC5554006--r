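#' Construct a genotype panel for an inbred line collection
#'
#' A `genotype_panel` holds biallelic marker calls for fully homozygous
#' (inbred) lines. Calls are coded 0/1 for the two homozygous states;
#' heterozygotes do not occur and missing calls are `NA`.
#'
#' @param calls Numeric matrix of 0/1/`NA` calls, genotypes in rows and
#'   markers in columns. Row and column names are used as genotype and
#'   marker identifiers when `genotype_ids`/`marker_ids` are not given.
#' @param genotype_ids,marker_ids Optional character vectors of unique
#'   labels overriding the dimnames of `calls`.
#'
#' @return An object of class `genotype_panel` with elements `calls`
#'   (named matrix), `genotype_ids` and `marker_ids`.
#' @export
genotype_panel <- function(calls, genotype_ids = NULL, marker_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(genotype_ids)) genotype_ids <- rownames(calls)
  if (is.null(marker_ids)) marker_ids <- colnames(calls)
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(calls)))
  genotype_ids <- as.character(genotype_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(genotype_ids)) stop("duplicate genotype ids", call. = FALSE)
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids", call. = FALSE)
  if (length(genotype_ids) != nrow(calls) || length(marker_ids) != ncol(calls)) {
    stop("id lengths do not match call matrix dimensions", call. = FALSE)
  }
  ok <- calls %in% c(0, 1) | is.na(calls)
  if (!all(ok)) {
    stop("calls must be 0, 1 or NA (inbred panel: no heterozygote codes)",
         call. = FALSE)
  }
  storage.mode(calls) <- "double"
  dimnames(calls) <- list(genotype_ids, marker_ids)
  structure(
    list(calls = calls, genotype_ids = genotype_ids, marker_ids = marker_ids),
    class = "genotype_panel"
  )
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$genotype_ids), " genotypes x ",
      length(x$marker_ids), " markers\n", sep = "")
  stats <- marker_stats(x)
  cat("  MAF range: ", sprintf("%.3f-%.3f", min(stats$maf), max(stats$maf)),
      "; mean missing rate: ", sprintf("%.4f", mean(stats$missing_rate)),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Per-marker allele-frequency and missingness summary
#'
#' Minor allele frequency is computed over non-missing calls as
#' `min(freq(1), freq(0))`, hence always in \[0, 0.5\].
#'
#' @param panel A [genotype_panel()].
#' @return A tibble with columns `marker_id`, `maf`, `missing_rate`.
#' @export
marker_stats <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$calls)
  n_miss <- colSums(is.na(panel$calls))
  p1 <- colMeans(panel$calls, na.rm = TRUE)
  p1[is.nan(p1)] <- NA_real_
  tibble::tibble(
    marker_id = panel$marker_ids,
    maf = pmin(p1, 1 - p1),
    missing_rate = n_miss / n
  )
}

#' Subset a genotype panel by marker and/or genotype
#'
#' @param panel A [genotype_panel()].
#' @param markers,genotypes Character vectors of ids (or logical/integer
#'   indices) to keep; `NULL` keeps all. Order of the panel is preserved
#'   for logical indices and follows the supplied order otherwise.
#' @return A [genotype_panel()].
#' @export
subset_panel <- function(panel, markers = NULL, genotypes = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  if (!is.null(genotypes)) calls <- calls[genotypes, , drop = FALSE]
  if (!is.null(markers)) calls <- calls[, markers, drop = FALSE]
  if (ncol(calls) == 0L) stop("no markers left after subsetting", call. = FALSE)
  genotype_panel(calls)
}

#' Validate a genetic map table
#'
#' A genetic map is a tibble with one row per marker: `marker_id`,
#' `chromosome` (opaque label, e.g. "1H".."7H"), `position_cM`
#' (non-negative real) and `mapped` (logical; markers without a position
#' have `mapped = FALSE` and `NA` position).
#'
#' @param map A data frame with the columns above (`mapped` optional;
#'   inferred from non-missing positions when absent).
#' @return The validated map as a tibble.
#' @export
genetic_map <- function(map) {
  map <- tibble::as_tibble(map)
  req <- c("marker_id", "chromosome", "position_cM")
  if (!all(req %in% names(map))) {
    stop("map must have columns marker_id, chromosome, position_cM", call. = FALSE)
  }
  if (!"mapped" %in% names(map)) map$mapped <- !is.na(map$position_cM)
  mapped <- map[map$mapped, , drop = FALSE]
  if (anyDuplicated(mapped$marker_id)) {
    stop("mapped markers must be unique in the genetic map", call. = FALSE)
  }
  if (any(!is.na(mapped$position_cM) & mapped$position_cM < 0)) {
    stop("genetic positions must be non-negative", call. = FALSE)
  }
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.character(map$chromosome)
  map
}
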