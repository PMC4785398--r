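#' OTU count tables
#'
#' An `otu_table` holds a non-negative integer count matrix with samples as
#' rows and OTUs as columns, plus an optional taxonomy map from OTU id to a
#' semicolon-separated ranked lineage
#' (`domain;phylum;class;order;family;genus`). It is the entry point of the
#' whole pipeline: everything upstream of the table (read merging, OTU
#' clustering at 97%, taxonomic annotation) is assumed done by standard
#' amplicon tools.
#'
#' @param counts integer matrix, samples x OTUs, with unique row and column
#'   names (sample ids and OTU ids).
#' @param taxonomy optional named character vector of lineages, names are
#'   OTU ids. OTUs without an entry are allowed.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   and `taxonomy`.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU1", "OTU2")))
#' tab <- otu_table(m)
#' n_samples(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have sample ids as rownames")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must have OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0L)) stop("counts contain negative entries")
  if (!is.null(taxonomy)) {
    taxonomy <- unlist(taxonomy)
    if (is.null(names(taxonomy)))
      stop("taxonomy must be a named vector (names are OTU ids)")
    extra <- setdiff(names(taxonomy), colnames(counts))
    if (length(extra))
      stop("taxonomy refers to unknown OTU ids: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s taxonomy\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

#' @rdname otu_table
#' @param table an `otu_table`.
#' @export
n_samples <- function(table) nrow(table$counts)

#' @rdname otu_table
#' @export
n_otus <- function(table) ncol(table$counts)

#' @rdname otu_table
#' @export
sample_depths <- function(table) rowSums(table$counts)

#' Read and write OTU tables as TSV
#'
#' The native on-disk format is a plain TSV: a header row, sample ids in the
#' first column (header `sample_id`) and one integer column per OTU.
#' `orientation = "otus"` reads/writes the transpose (OTUs as rows, samples
#' as columns, first header cell `otu_id`), as produced by some clustering
#' pipelines. Round trips are exact: `read_otu_table(write_otu_table(t))`
#' reproduces `t` bit for bit.
#'
#' @param path file path.
#' @param orientation `"samples"` (rows are samples, default) or `"otus"`.
#' @param taxonomy_path optional taxonomy TSV (`otu_id <TAB> lineage`,
#'   no header) read alongside the table.
#' @return `read_otu_table` returns an [otu_table]; the writers return the
#'   path invisibly.
#' @export
read_otu_table <- function(path, orientation = c("samples", "otus"),
                           taxonomy_path = NULL) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", fill = FALSE)
  if (ncol(df) < 2) stop("table must have at least one count column")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  if (anyNA(num)) stop("non-numeric cell in count table")
  if (any(num != round(num))) stop("non-integer count in table")
  if (any(num < 0)) stop("negative count in table")
  rownames(num) <- ids
  if (orientation == "otus") num <- t(num)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  otu_table(num, taxonomy = taxonomy)
}

#' @rdname read_otu_table
#' @param table an [otu_table].
#' @export
write_otu_table <- function(table, path, orientation = c("samples", "otus")) {
  orientation <- match.arg(orientation)
  m <- table$counts
  if (orientation == "otus") m <- t(m)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- if (orientation == "samples") "sample_id" else "otu_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_otu_table
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", fill = FALSE)
  if (ncol(df) != 2) stop("taxonomy file must have two columns")
  if (anyDuplicated(df[[1]])) stop("duplicate OTU ids in taxonomy")
  setNames(df[[2]], df[[1]])
}

#' @rdname read_otu_table
#' @param taxonomy named lineage vector as stored in an [otu_table].
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(data.frame(names(taxonomy), unname(taxonomy)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `location` (e.g. the village
#' of capture), `class_label` (M = male, FBF = blood-fed female,
#' FNBF = non-blood-fed female) and logical `pooled` (TRUE for samples made
#' by pooling several males).
#'
#' @param path file path.
#' @param table optional companion [otu_table]; if given, every metadata
#'   sample id must appear in the table.
#' @return a data.frame with the four columns above.
#' @export
read_metadata <- function(path, table = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", fill = FALSE)
  need <- c("sample_id", "location", "class_label", "pooled")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  df$pooled <- as.logical(df$pooled)
  if (!is.null(table)) {
    unknown <- setdiff(df$sample_id, rownames(table$counts))
    if (length(unknown))
      stop("metadata sample ids absent from table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  df
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Ranked lineage fields; CREST/SILVA-style "g__" prefixes are tolerated.
.lineage_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  lapply(parts, function(p) sub("^[a-z]__", "", trimws(p)))
}

#' Extract one taxonomic rank from lineage strings
#'
#' @param taxonomy named lineage vector.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return named character vector of taxon names at that rank (NA where the
#'   lineage is too short).
#' @export
lineage_at_rank <- function(taxonomy, rank) {
  rank <- tolower(rank)
  i <- match(rank, .lineage_ranks)
  if (is.na(i)) stop("unknown rank: ", rank)
  vapply(split_lineage(taxonomy),
         function(p) if (length(p) >= i) p[[i]] else NA_character_,
         character(1))
}

#' Subset an OTU table to one taxon
#'
#' Keeps exactly the OTUs whose lineage at `rank` equals `name`
#' (case-insensitive). All samples are retained, including samples whose
#' subset row becomes all zero — an absent taxon yields a valid 0-OTU table,
#' not an error. Used for the genus-level follow-up analyses (e.g. the
#' *Acinetobacter*-only ordination and the skin-bacteria genus screen).
#'
#' @param table an [otu_table] with taxonomy.
#' @param rank taxonomic rank to match at.
#' @param name taxon name.
#' @return an [otu_table] with the matching OTU columns only.
#' @export
subset_by_taxon <- function(table, rank, name) {
  if (is.null(table$taxonomy)) stop("table has no taxonomy")
  at <- lineage_at_rank(table$taxonomy, rank)
  keep <- names(at)[!is.na(at) & tolower(at) == tolower(name)]
  keep <- intersect(colnames(table$counts), keep)
  otu_table(table$counts[, keep, drop = FALSE],
            taxonomy = if (length(keep)) table$taxonomy[keep])
}

#' Per-sample relative abundance of a taxon
#'
#' Fraction of each sample's reads assigned to OTUs of one taxon,
#' e.g. the per-mosquito *Wolbachia* fraction.
#'
#' @inheritParams subset_by_taxon
#' @return named numeric vector in `[0, 1]`, one entry per sample.
#' @export
relative_abundance <- function(table, rank, name) {
  depths <- sample_depths(table)
  if (any(depths == 0))
    stop("zero-depth sample(s): ",
         paste(names(depths)[depths == 0], collapse = ", "))
  sub <- subset_by_taxon(table, rank, name)
  rowSums(sub$counts) / depths
}

#' Pool samples by summing counts
#'
#' Element-wise sums the count rows of each group into one new sample (the
#' study pooled physically small males, five per pool, to get enough DNA).
#' Pooled samples replace their members at the position of the first member;
#' ungrouped samples are untouched. Total read count is conserved.
#'
#' @param table an [otu_table].
#' @param groups list of character vectors of sample ids; groups must be
#'   disjoint.
#' @param new_ids character vector, one id per group.
#' @return an [otu_table].
#' @export
pool_samples <- function(table, groups, new_ids) {
  if (length(groups) != length(new_ids))
    stop("need one new id per group")
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) stop("groups overlap")
  unknown <- setdiff(all_members, rownames(table$counts))
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))
  m <- table$counts
  keep_order <- rownames(m)
  pooled_rows <- lapply(groups, function(g)
    colSums(m[g, , drop = FALSE]))
  out_ids <- character(0)
  rows <- list()
  consumed <- character(0)
  for (id in keep_order) {
    if (id %in% consumed) next
    gi <- which(vapply(groups, function(g) id %in% g, logical(1)))
    if (length(gi)) {
      rows[[length(rows) + 1L]] <- pooled_rows[[gi]]
      out_ids <- c(out_ids, new_ids[gi])
      consumed <- c(consumed, groups[[gi]])
    } else {
      rows[[length(rows) + 1L]] <- m[id, ]
      out_ids <- c(out_ids, id)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out_ids
  otu_table(out, taxonomy = table$taxonomy)
}
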