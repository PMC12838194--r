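#' Construct a qPCR gene-chip table
#'
#' Holds cycle-threshold (Ct) values from a high-throughput qPCR array
#' (SmartChip-style) quantifying functional genes of the carbon, nitrogen,
#' phosphorus and sulfur cycles, plus a 16S rRNA internal reference. Missing
#' Ct means non-detection (censoring), never zero copies. Per-sample absolute
#' 16S copy numbers (copies/g, from a separate absolute quantification)
#' anchor the relative scale.
#'
#' @param ct numeric matrix of Ct values, genes in rows, samples in columns;
#'   `NA` marks non-detection. Present values must lie in (0, 45).
#' @param cycle character vector per gene, one of `"C"`, `"N"`, `"P"`, `"S"`,
#'   `"16S"`. Exactly one gene must be labelled `"16S"`.
#' @param group character vector per sample, `"cultivated"` or `"control"`.
#' @param abs_16s positive numeric vector per sample: absolute 16S rRNA
#'   copies per gram.
#' @return An object of class `genechip_table`.
#' @export
genechip_table <- function(ct, cycle, group, abs_16s) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ct must have gene row names and sample column names")
  }
  x <- structure(
    list(ct = ct,
         cycle = stats::setNames(as.character(cycle), rownames(ct)),
         group = stats::setNames(as.character(group), colnames(ct)),
         abs_16s = stats::setNames(as.numeric(abs_16s), colnames(ct))),
    class = "genechip_table")
  validate_genechip_table(x)
}

validate_genechip_table <- function(x) {
  ct <- x$ct
  dup <- unique(rownames(ct)[duplicated(rownames(ct))])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(ct)[duplicated(colnames(ct))])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (length(x$cycle) != nrow(ct)) stop("one cycle label per gene required")
  bad <- setdiff(unique(x$cycle), c("C", "N", "P", "S", "16S"))
  if (length(bad)) stop("unknown cycle label(s): ", paste(bad, collapse = ", "))
  n16 <- sum(x$cycle == "16S")
  if (n16 == 0) stop("no 16S reference gene in table")
  if (n16 > 1) stop("more than one 16S reference gene: ",
                    paste(names(x$cycle)[x$cycle == "16S"], collapse = ", "))
  present <- ct[!is.na(ct)]
  if (any(present <= 0 | present >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  if (length(x$group) != ncol(ct) || anyNA(x$group)) {
    stop("every sample needs a group label")
  }
  bad <- setdiff(unique(x$group), c("cultivated", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (length(x$abs_16s) != ncol(ct) || anyNA(x$abs_16s) || any(x$abs_16s <= 0)) {
    stop("abs_16s must be positive for every sample")
  }
  x
}

#' @export
print.genechip_table <- function(x, ...) {
  cat(sprintf("Gene-chip Ct table: %d genes x %d samples\n",
              nrow(x$ct), ncol(x$ct)))
  cat("  cycles: ", paste(sprintf("%s=%d", names(table(x$cycle)),
                                  table(x$cycle)), collapse = ", "), "\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(x$group)),
                                  table(x$group)), collapse = ", "), "\n")
  cat(sprintf("  non-detections: %d of %d wells\n",
              sum(is.na(x$ct)), length(x$ct)))
  invisible(x)
}

#' Read a gene-chip Ct table from CSV plus a 16S sidecar
#'
#' The CSV has columns `gene,cycle,<sample...>`; empty cells are
#' non-detections. The sidecar TSV has columns `sample_id`, `group`,
#' `copies_per_g` with the absolute 16S quantification per sample.
#'
#' @param path path to the Ct CSV.
#' @param abs16s_path path to the 16S sidecar TSV.
#' @return A [genechip_table()].
#' @export
read_genechip_table <- function(path, abs16s_path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene", "cycle") %in% names(raw))) {
    stop("chip CSV must have 'gene' and 'cycle' columns")
  }
  sample_cols <- setdiff(names(raw), c("gene", "cycle"))
  ct <- as.matrix(raw[sample_cols])
  storage.mode(ct) <- "double"
  rownames(ct) <- raw$gene
  side <- utils::read.delim(abs16s_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "copies_per_g")
  if (!all(need %in% names(side))) {
    stop("16S sidecar must have columns: ", paste(need, collapse = ", "))
  }
  missing_side <- setdiff(sample_cols, side$sample_id)
  if (length(missing_side)) {
    stop("sample(s) without 16S sidecar entry: ",
         paste(missing_side, collapse = ", "))
  }
  idx <- match(sample_cols, side$sample_id)
  genechip_table(ct, cycle = raw$cycle, group = side$group[idx],
                 abs_16s = side$copies_per_g[idx])
}

#' Write a gene-chip table to CSV plus a 16S sidecar
#'
#' @param x a [genechip_table()].
#' @param path output path for the Ct CSV.
#' @param abs16s_path output path for the 16S sidecar TSV.
#' @return Invisibly, `x`.
#' @export
write_genechip_table <- function(x, path, abs16s_path) {
  stopifnot(inherits(x, "genechip_table"))
  df <- data.frame(gene = rownames(x$ct), cycle = unname(x$cycle),
                   x$ct, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  side <- data.frame(sample_id = colnames(x$ct), group = unname(x$group),
                     copies_per_g = unname(x$abs_16s))
  utils::write.table(side, abs16s_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
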