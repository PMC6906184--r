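# Quantification: read-to-model assignment with multi-compatibility
# down-weighting (1/k), TMM between-library normalisation, equal-depth
# downsampling and matrix export.

new_expression_matrix <- function(values, transform = "raw",
                                  library_sizes = colSums(values),
                                  extra = list()) {
  structure(c(list(values = values, library_sizes = library_sizes,
                   transform = transform), extra),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$transform, "): ", nrow(x$values),
      " transcripts x ", ncol(x$values), " libraries\n", sep = "")
  invisible(x)
}

#' Assign reads to transcript models with down-weighting
#'
#' A read whose chain is identical to a model chain (or, for reads without
#' complete ends, a contiguous truncated sub-chain of the model) is
#' compatible with it. A read compatible with exactly one model contributes
#' 1 to that model; a read compatible with `k` models contributes `1/k` to
#' each, so column sums equal the number of assigned reads per library.
#'
#' @param paths an `exon_paths` data.frame (all accepted read paths).
#' @param models `transcript_models` (typically the filtered set).
#' @return an `expression_matrix` (transform `"raw"`, transcripts x
#'   libraries) with `n_unassigned` in the object.
#' @export
assign_reads <- function(paths, models) {
  libs <- sort(unique(ifelse(is.na(paths$library_id), "library1",
                             paths$library_id)))
  paths$library_id[is.na(paths$library_id)] <- "library1"
  ids <- if (!is.null(models$transcript_id)) models$transcript_id else models$chain
  vals <- matrix(0, nrow = nrow(models), ncol = length(libs),
                 dimnames = list(ids, libs))
  unassigned <- 0L
  # reads with the same (chain, complete flag, library) are interchangeable
  grp <- paste(paths$chain, paths$complete_ends, paths$library_id, sep = "\r")
  tab <- table(grp)
  for (g in names(tab)) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    ck <- parts[1]; complete <- parts[2] == "TRUE"; lib <- parts[3]
    nreads <- as.integer(tab[[g]])
    compat <- if (complete) which(models$chain == ck) else
      which(vapply(models$chain, function(mk) chain_is_infix(ck, mk), logical(1)))
    k <- length(compat)
    if (k == 0L) { unassigned <- unassigned + nreads; next }
    vals[compat, lib] <- vals[compat, lib] + nreads / k
  }
  new_expression_matrix(vals, "raw", extra = list(n_unassigned = unassigned))
}

#' TMM between-library normalisation
#'
#' Computes trimmed-mean-of-M-values scaling factors (via
#' `edgeR::calcNormFactors`, the published procedure with 30 percent
#' trimming on log-ratios, 5 percent on average log-abundance and
#' precision weighting, factors rescaled to geometric mean 1) and returns
#' the normalised matrix `count / (library_size * factor)`.
#'
#' @param em an `expression_matrix` with raw counts.
#' @param logratio_trim,sum_trim,do_weighting TMM parameters.
#' @return list with `factors` (per-library scaling factors), `ref`
#'   (reference library id, the library whose upper-quartile/total ratio is
#'   closest to the mean) and `matrix` (normalised `expression_matrix`).
#' @export
tmm_normalise <- function(em, logratio_trim = 0.3, sum_trim = 0.05,
                          do_weighting = TRUE) {
  v <- em$values
  if (ncol(v) < 2L) stop("TMM needs at least 2 libraries")
  if (any(colSums(v) == 0)) stop("degenerate library: all-zero counts")
  f <- edgeR::calcNormFactors(v, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim, doWeighting = do_weighting)
  names(f) <- colnames(v)
  lib <- colSums(v)
  # reference library: upper-quartile/total ratio closest to the mean
  uq <- apply(v, 2L, function(x) quantile(x, 0.75)) / lib
  ref <- colnames(v)[which.min(abs(uq - mean(uq)))]
  norm <- sweep(v, 2L, lib * f, "/")
  list(factors = f, ref = ref,
       matrix = new_expression_matrix(norm, "tmm", library_sizes = lib,
                                      extra = list(factors = f, ref = ref)))
}

#' Downsample libraries to equal depth
#'
#' Samples reads without replacement from each library down to the
#' smallest library depth; deterministic given `seed`.
#'
#' @param paths an `exon_paths` data.frame (one row per read).
#' @param seed integer seed.
#' @return the downsampled `exon_paths` (equal reads per library).
#' @export
downsample_reads <- function(paths, seed) {
  stopifnot(!missing(seed))
  lib <- ifelse(is.na(paths$library_id), "library1", paths$library_id)
  depth <- min(table(lib))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  keep <- unlist(lapply(split(seq_len(nrow(paths)), lib), function(idx)
    sort(sample(idx, depth))), use.names = FALSE)
  out <- paths[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(paths)
  out
}

#' Log10 transform with pseudocount
#'
#' @param em an `expression_matrix`.
#' @param pseudocount added before taking log10 (default 1, so zeros map
#'   to zero).
#' @return a transformed `expression_matrix`.
#' @export
log_transform <- function(em, pseudocount = 1) {
  new_expression_matrix(log10(em$values + pseudocount), "log10",
                        library_sizes = em$library_sizes)
}

#' Per-library proportions
#'
#' @param em an `expression_matrix` of raw counts.
#' @return matrix of per-column proportions (columns sum to 1).
#' @export
proportions_matrix <- function(em) {
  sweep(em$values, 2L, pmax(colSums(em$values), .Machine$double.eps), "/")
}

#' Export expression matrices
#'
#' Writes raw, TMM-normalised, log10 and per-library proportion tables as
#' TSV with stable row/column order, plus a JSON run-metadata file (seed,
#' thresholds, normalisation factors) when `metadata` is supplied.
#'
#' @param raw,normalised,logged `expression_matrix` objects (`normalised`
#'   and `logged` optional).
#' @param prefix output path prefix.
#' @param metadata optional list serialised to `<prefix>.metadata.json`.
#' @export
export_matrices <- function(raw, normalised = NULL, logged = NULL, prefix,
                            metadata = NULL) {
  wr <- function(m, suffix) {
    tab <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
    write.table(tab, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(raw$values, ".raw.tsv")
  wr(proportions_matrix(raw), ".proportions.tsv")
  if (!is.null(normalised)) wr(normalised$values, ".tmm.tsv")
  if (!is.null(logged)) wr(logged$values, ".log10.tsv")
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(prefix, ".metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
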