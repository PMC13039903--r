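#' Construct an abundance table
#'
#' The central data container: a samples-by-taxa matrix of relative
#' abundances (rows renormalized to sum to 1), optional integer counts, and
#' per-taxon prevalence bookkeeping.
#'
#' @param rel_abundance numeric matrix, samples x taxa; rows are renormalized.
#' @param counts optional non-negative integer matrix of the same shape.
#' @param sample_ids,taxon_ids identifiers; default from dimnames.
#' @return an object of class `abundance_table` with fields `rel_abundance`,
#'   `counts`, `sample_ids`, `taxon_ids`, `prevalence`.
#' @export
abundance_table <- function(rel_abundance, counts = NULL,
                            sample_ids = rownames(rel_abundance),
                            taxon_ids = colnames(rel_abundance)) {
  rel_abundance <- as.matrix(rel_abundance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(rel_abundance)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(rel_abundance)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (any(!is.finite(rel_abundance))) stop("non-finite abundances")
  if (any(rel_abundance < 0)) stop("negative abundances")
  rs <- rowSums(rel_abundance)
  if (any(rs <= 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(sample_ids[rs <= 0], collapse = ", "))
  }
  rel_abundance <- rel_abundance / rs
  dimnames(rel_abundance) <- list(sample_ids, taxon_ids)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == dim(rel_abundance)))
    if (any(counts < 0)) stop("negative counts")
    dimnames(counts) <- dimnames(rel_abundance)
  }
  structure(
    list(rel_abundance = rel_abundance, counts = counts,
         sample_ids = sample_ids, taxon_ids = taxon_ids,
         prevalence = colMeans(rel_abundance > 0)),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", length(x$sample_ids), "samples x",
      length(x$taxon_ids), "taxa;",
      if (is.null(x$counts)) "relative abundances only" else "with counts", "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$rel_abundance)

#' Filter taxa by prevalence
#'
#' Removes ultra-low-prevalence taxa: a taxon is dropped when the fraction of
#' samples in which it is observed is strictly below `min_prev` (the
#' conventional 10% floor by default). Relative abundances are not
#' renormalized after filtering unless `renormalize = TRUE`, so retained
#' abundances keep their original scale.
#'
#' @param table an `abundance_table`.
#' @param min_prev minimum prevalence fraction in \[0, 1).
#' @param renormalize re-close rows after filtering (default FALSE).
#' @return a filtered `abundance_table`; the retained taxa are recorded in
#'   attribute `"retained"`.
#' @export
filter_prevalence <- function(table, min_prev = 0.10, renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"),
            min_prev >= 0, min_prev < 1)
  keep <- table$prevalence >= min_prev
  if (!any(keep)) stop("prevalence filter removed all taxa")
  rel <- table$rel_abundance[, keep, drop = FALSE]
  out <- structure(
    list(rel_abundance = if (renormalize) rel / rowSums(rel) else rel,
         counts = if (is.null(table$counts)) NULL else
           table$counts[, keep, drop = FALSE],
         sample_ids = table$sample_ids,
         taxon_ids = table$taxon_ids[keep],
         prevalence = table$prevalence[keep]),
    class = "abundance_table"
  )
  attr(out, "retained") <- table$taxon_ids[keep]
  out
}

#' Read and align a cohort from its three tables
#'
#' Reads abundance (first column sample ID, remaining columns taxa), sample
#' metadata and diet TSV tables, restricts all three to their common samples
#' (inner join on the identifier column), row-normalizes abundances, and
#' reports dropped samples.
#'
#' @param abundance_path,metadata_path,diet_path TSV paths.
#' @param id_col identifier column name shared by the tables (default
#'   `"sample_id"`).
#' @return a list of class `cohort_dataset` with elements `abundance`
#'   (an `abundance_table`), `metadata`, `diet` (data.frames aligned to the
#'   same sample order) and `dropped` (identifiers absent from some table).
#' @export
read_cohort <- function(abundance_path, metadata_path, diet_path,
                        id_col = "sample_id") {
  ab <- read_tsv_table(abundance_path)
  md <- read_tsv_table(metadata_path)
  dt <- read_tsv_table(diet_path)
  if (names(ab)[1] != id_col && !(id_col %in% names(ab))) {
    names(ab)[1] <- id_col    # first column is the identifier by dialect
  }
  for (nm in c("metadata", "diet")) {
    tab <- if (nm == "metadata") md else dt
    if (!(id_col %in% names(tab))) {
      stop("format error: table '", nm, "' lacks identifier column '", id_col, "'")
    }
  }
  ids <- Reduce(intersect, list(ab[[id_col]], md[[id_col]], dt[[id_col]]))
  if (length(ids) == 0) stop("input error: no overlapping samples across tables")
  all_ids <- unique(c(ab[[id_col]], md[[id_col]], dt[[id_col]]))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped)) {
    warning(length(dropped), " sample(s) absent from at least one table dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  mat <- as.matrix(ab[match(ids, ab[[id_col]]), setdiff(names(ab), id_col), drop = FALSE])
  rownames(mat) <- ids
  structure(
    list(abundance = abundance_table(mat),
         metadata = md[match(ids, md[[id_col]]), , drop = FALSE],
         diet = dt[match(ids, dt[[id_col]]), , drop = FALSE],
         dropped = dropped),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", length(x$abundance$sample_ids), "aligned samples;",
      length(x$dropped), "dropped\n")
  invisible(x)
}
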