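#' Construct an OTU table
#'
#' The central data container of the pipeline: a samples-by-OTUs matrix of
#' non-negative integer read counts, with per-sample `group`
#' (`"cultivated"` / `"control"`) and `domain` (`"prokaryote"` /
#' `"eukaryote"`) labels and optional per-OTU taxonomy strings
#' (semicolon-delimited ranks, phylum extractable).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Row and
#'   column names are used as sample and OTU ids.
#' @param group character vector of per-sample group labels, one of
#'   `"cultivated"` or `"control"`.
#' @param domain character vector of per-sample domain labels, one of
#'   `"prokaryote"` or `"eukaryote"`.
#' @param taxonomy optional character vector of per-OTU lineage strings
#'   (semicolon-delimited ranks).
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `group`, `domain`, `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2", "OTU_3")))
#' ot <- otu_table(m, group = c("cultivated", "control"),
#'                 domain = c("prokaryote", "prokaryote"))
#' ot
#' @export
otu_table <- function(counts, group, domain, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample row names and OTU column names")
  }
  storage.mode(counts) <- "double"
  x <- structure(
    list(counts = counts,
         group = stats::setNames(as.character(group), rownames(counts)),
         domain = stats::setNames(as.character(domain), rownames(counts)),
         taxonomy = if (is.null(taxonomy)) NULL else
           stats::setNames(as.character(taxonomy), colnames(counts))),
    class = "otu_table")
  validate_otu_table(x)
}

validate_otu_table <- function(x) {
  counts <- x$counts
  sid <- rownames(counts)
  oid <- colnames(counts)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  dup <- unique(oid[duplicated(oid)])
  if (length(dup)) stop("duplicate OTU id(s): ", paste(dup, collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (length(x$group) != nrow(counts) || anyNA(x$group)) {
    stop("every sample needs a group label")
  }
  if (length(x$domain) != nrow(counts) || anyNA(x$domain)) {
    stop("every sample needs a domain label")
  }
  bad <- setdiff(unique(x$group), c("cultivated", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$domain), c("prokaryote", "eukaryote"))
  if (length(bad)) stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  if (!is.null(x$taxonomy) && length(x$taxonomy) != ncol(counts)) {
    stop("taxonomy must have one entry per OTU")
  }
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("  groups: ", paste(sprintf("%s=%d", names(table(x$group)),
                                  table(x$group)), collapse = ", "), "\n")
  cat("  domains:", paste(sprintf("%s=%d", names(table(x$domain)),
                                  table(x$domain)), collapse = ", "), "\n")
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param x an [otu_table()].
#' @return Matrix of the same shape as `x$counts` with rows summing to 1.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(x$counts)[tot == 0], collapse = ", "))
  }
  sweep(x$counts, 1, tot, "/")
}

#' Read an OTU table from TSV plus a metadata sidecar
#'
#' On disk the table follows the dominant amplicon convention: OTUs as rows,
#' samples as columns, first column `#OTU_ID`, optional final column
#' `taxonomy`. Sample metadata (columns `sample_id`, `group`, `domain`) lives
#' in a separate TSV. In memory the orientation is samples x OTUs.
#'
#' @param path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "#OTU_ID" && names(raw)[1] != "X.OTU_ID") {
    stop("first column must be #OTU_ID, got: ", names(raw)[1])
  }
  otu_ids <- as.character(raw[[1]])
  dup <- unique(otu_ids[duplicated(otu_ids)])
  if (length(dup)) stop("duplicate OTU id(s): ", paste(dup, collapse = ", "))
  taxonomy <- NULL
  data_cols <- raw[-1]
  if ("taxonomy" %in% names(data_cols)) {
    taxonomy <- as.character(data_cols$taxonomy)
    data_cols <- data_cols[names(data_cols) != "taxonomy"]
  }
  counts <- t(as.matrix(data_cols))
  colnames(counts) <- otu_ids
  if (anyNA(suppressWarnings(as.numeric(counts)))) {
    stop("non-numeric counts in ", path)
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "domain")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  idx <- match(rownames(counts), meta$sample_id)
  otu_table(counts, group = meta$group[idx], domain = meta$domain[idx],
            taxonomy = taxonomy)
}

#' Write an OTU table to TSV plus a metadata sidecar
#'
#' @param x an [otu_table()].
#' @param path output path for the counts TSV (OTUs as rows).
#' @param metadata_path output path for the sample metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_otu_table <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(`#OTU_ID` = colnames(x$counts), t(x$counts),
                   check.names = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = rownames(x$counts),
                     group = unname(x$group), domain = unname(x$domain))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
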