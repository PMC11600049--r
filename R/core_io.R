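# Data model and readers/writers for the external formats the pipeline
# touches: 10x-style sparse triplet matrices, metadata TSV, GMT gene sets,
# UCSC cytoBand tables and ligand-receptor pair CSVs.
#
# Conventions: all in-memory matrices are cells-as-rows; genomic coordinates
# are 0-based half-open; gene identity is the (case-sensitive) symbol string.

#' Construct a validated expression dataset
#'
#' The central container of the pipeline: a sparse non-negative integer
#' UMI count matrix (cells x genes) plus one metadata record per cell.
#'
#' @param counts Matrix or sparse Matrix of non-negative integer counts,
#'   cells as rows, genes as columns.
#' @param gene_ids Character vector of unique gene symbols, one per column.
#' @param cell_ids Character vector of unique cell barcodes, one per row.
#' @param meta Data frame with one row per cell and columns `sample_id`,
#'   `group` (one of [tme_groups()]), `cluster`, and optionally `cell_type`.
#'   Rows are matched to `cell_ids` via a `cell_id` column if present,
#'   otherwise positionally.
#' @param norm Optional numeric matrix of the same shape holding
#'   natural-log normalised expression (see [normalize_log1p()]).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(counts, gene_ids, cell_ids, meta, norm = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    stopf("count matrix is %d x %d but %d cell ids and %d gene ids were given",
          nrow(counts), ncol(counts), length(cell_ids), length(gene_ids))
  }
  if (anyDuplicated(cell_ids)) {
    stopf("duplicated cell ids: %s",
          paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicated gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stopf("counts must be non-negative integers")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "cluster")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stopf("meta is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if ("cell_id" %in% names(meta)) {
    if (anyDuplicated(meta$cell_id)) stopf("meta has duplicated cell_id records")
    idx <- match(cell_ids, meta$cell_id)
    if (anyNA(idx)) {
      stopf("meta lacks a record for cell(s): %s",
            paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "))
    }
    if (nrow(meta) != length(cell_ids)) {
      stopf("meta has %d records for %d cells", nrow(meta), length(cell_ids))
    }
    meta <- meta[idx, , drop = FALSE]
  } else if (nrow(meta) != length(cell_ids)) {
    stopf("meta has %d rows but there are %d cells", nrow(meta), length(cell_ids))
  }
  meta$cell_id <- cell_ids
  rownames(meta) <- cell_ids
  bad <- setdiff(unique(meta$group), tme_groups())
  if (length(bad)) {
    stopf("unknown group label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(tme_groups(), collapse = ", "))
  }
  if (!is.null(norm)) {
    norm <- as(Matrix::Matrix(norm, sparse = TRUE), "CsparseMatrix")
    if (!identical(dim(norm), dim(counts))) {
      stopf("norm matrix shape %d x %d does not match counts %d x %d",
            nrow(norm), ncol(norm), nrow(counts), ncol(counts))
    }
    dimnames(norm) <- list(cell_ids, gene_ids)
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         meta = meta, norm = norm),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes (%s normalised)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (is.null(x$norm)) "not" else "log1p"))
  cat(sprintf("  groups: %s\n",
              paste(names(table(x$meta$group)), collapse = ", ")))
  cat(sprintf("  clusters: %d\n", length(unique(x$meta$cluster))))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Read an expression dataset from 10x-style triplet files
#'
#' Expects a MatrixMarket file with genes as rows and cells as columns (the
#' on-disk 10x dialect), a features file (one gene symbol per line), a
#' barcodes file (one barcode per line), and a tab-separated metadata table
#' with header columns `cell_id`, `sample_id`, `group`, `cluster`.
#'
#' @param matrix_path,features_path,barcodes_path,meta_path File paths.
#' @return An [expression_dataset()]; cell order follows the barcodes file.
#' @export
read_dataset <- function(matrix_path, features_path, barcodes_path, meta_path) {
  for (p in c(matrix_path, features_path, barcodes_path, meta_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  m <- Matrix::readMM(matrix_path)
  features <- read_first_column(features_path)
  barcodes <- read_first_column(barcodes_path)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stopf(paste0("matrix is %d x %d but features/barcodes list %d genes and ",
                 "%d cells"), nrow(m), ncol(m), length(features), length(barcodes))
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  expression_dataset(Matrix::t(m), gene_ids = features, cell_ids = barcodes,
                     meta = meta)
}

read_first_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an expression dataset as 10x-style triplet files
#'
#' Emits `matrix.mtx` (genes x cells), `features.tsv`, `barcodes.tsv` and
#' `meta.tsv` into `out_dir`, readable back by [read_dataset()].
#'
#' @param dataset An `ExpressionDataset`.
#' @param out_dir Output directory, created if absent.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stopf("cannot create directory: %s", out_dir)
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             meta = file.path(out_dir, "meta.tsv"))
  Matrix::writeMM(Matrix::t(dataset$counts), paths[["matrix"]])
  writeLines(dataset$gene_ids, paths[["features"]])
  writeLines(dataset$cell_ids, paths[["barcodes"]])
  meta <- dataset$meta
  meta <- meta[, c("cell_id", setdiff(names(meta), "cell_id")), drop = FALSE]
  utils::write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Subset an expression dataset to a set of cells
#'
#' @param dataset An `ExpressionDataset`.
#' @param cells Cell ids to keep (order preserved as given).
#' @return The subsetted dataset.
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  missing_ <- setdiff(cells, dataset$cell_ids)
  if (length(missing_)) {
    stopf("unknown cell id(s): %s", paste(utils::head(missing_, 5), collapse = ", "))
  }
  expression_dataset(dataset$counts[cells, , drop = FALSE],
                     gene_ids = dataset$gene_ids, cell_ids = cells,
                     meta = dataset$meta[cells, , drop = FALSE],
                     norm = if (is.null(dataset$norm)) NULL else
                       dataset$norm[cells, , drop = FALSE])
}

#' Read a GMT gene-set file
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  sets <- lapply(fields, function(f) {
    genes <- f[-c(1L, 2L)]
    genes[nzchar(genes)]
  })
  names(sets) <- names_
  gene_set_collection(sets)
}

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return The validated list with class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stopf("gene set names must be unique")
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stopf("gene set '%s' is empty", nm)
    if (anyDuplicated(sets[[nm]])) {
      stopf("gene set '%s' contains duplicate genes", nm)
    }
  }
  structure(sets, class = "GeneSetCollection")
}

#' Read a UCSC-style cytoBand table
#'
#' Tab-separated columns: chrom, start, end, band, (optional stain); no
#' header. Coordinates are 0-based half-open; bands must begin with 'p' or
#' 'q' and be non-overlapping within a chromosome.
#'
#' @param path cytoBand file path.
#' @return Data frame (class `CytobandTable`) with columns chrom, start,
#'   end, band, arm; sorted by chrom then start.
#' @export
read_cytoband <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stopf("cytoband table needs >= 4 columns, got %d", ncol(tab))
  names(tab)[1:4] <- c("chrom", "start", "end", "band")
  cytoband_table(tab[, 1:4])
}

#' Construct a validated cytoband table
#'
#' @param tab Data frame with columns chrom, start, end, band.
#' @return Validated, sorted data frame with an `arm` column added.
#' @export
cytoband_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(tab)))
  arm <- substr(tab$band, 1, 1)
  bad <- !arm %in% c("p", "q")
  if (any(bad)) {
    stopf("band(s) not starting with p or q: %s",
          paste(utils::head(tab$band[bad], 5), collapse = ", "))
  }
  if (any(tab$end <= tab$start)) stopf("cytoband with end <= start")
  tab$arm <- arm
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stopf("overlapping cytobands on %s", ch)
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("CytobandTable", "data.frame")
  tab
}

#' Read a ligand-receptor pair table
#'
#' CSV with header columns `pair_name`, `ligand`, `receptor`; multi-subunit
#' receptors are '+'-joined, e.g. `CD74+CD44` for the MIF-(CD74+CD44) pair.
#'
#' @param path CSV file path.
#' @return Data frame (class `LRDatabase`) with a `receptor_subunits`
#'   list-column.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("pair_name", "ligand", "receptor")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stopf("LR table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  lr_database(tab)
}

#' Construct a validated ligand-receptor database
#'
#' @param tab Data frame with columns pair_name, ligand, receptor
#'   ('+'-joined subunits).
#' @return Validated data frame with a `receptor_subunits` list-column.
#' @export
lr_database <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$pair_name)) {
    stopf("duplicated pair_name: %s",
          paste(unique(tab$pair_name[duplicated(tab$pair_name)]), collapse = ", "))
  }
  subunits <- strsplit(tab$receptor, "+", fixed = TRUE)
  empty <- vapply(subunits, function(s) length(s) == 0 || any(!nzchar(s)),
                  logical(1))
  if (any(empty)) {
    stopf("pair(s) with empty receptor subunit list: %s",
          paste(tab$pair_name[empty], collapse = ", "))
  }
  tab$receptor_subunits <- subunits
  class(tab) <- c("LRDatabase", "data.frame")
  tab
}
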