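#' Generate a sparse count matrix with planted per-gene prevalence
#'
#' Each gene is expressed (count > 0) in a Binomial(`n_cells`, prevalence)
#' subset of cells; expressed entries are `1 + Poisson(mu * depth)` counts,
#' with per-cell depth factors drawn lognormally, so the empirical nonzero
#' fraction matches the planted prevalence up to binomial sampling error.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param prevalence Per-gene expression prevalence in `[0, 1]`; recycled to
#'   `n_genes`.
#' @param mean_count Mean extra counts of an expressed entry at unit depth.
#' @param depth_sdlog Lognormal sd of per-cell depth factors.
#' @param seed Integer seed.
#' @return A list with `counts` (a `dgCMatrix`, genes x cells, dimnames
#'   `gene1..`/`cell1..`) and `truth` (tibble of planted prevalences).
#' @export
gen_count_matrix <- function(n_genes, n_cells, prevalence,
                             mean_count = 2, depth_sdlog = 0.3, seed = 1L) {
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  prevalence <- rep_len(prevalence, n_genes)
  withr::with_seed(seed, {
    depth <- stats::rlnorm(n_cells, 0, depth_sdlog)
    nnz_per_gene <- stats::rbinom(n_genes, n_cells, prevalence)
    cols <- purrr::map(seq_len(n_genes), function(g) {
      if (nnz_per_gene[g] == 0L) integer(0) else
        sort(sample.int(n_cells, nnz_per_gene[g]))
    })
    j <- unlist(cols)
    i <- rep.int(seq_len(n_genes), lengths(cols))
    x <- 1 + stats::rpois(length(j), mean_count * depth[j])
  })
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = x, dims = c(n_genes, n_cells),
    dimnames = list(paste0("gene", seq_len(n_genes)),
                    paste0("cell", seq_len(n_cells)))
  )
  list(
    counts = m,
    truth = tibble::tibble(gene = rownames(m), prevalence = prevalence,
                           n_expressing = nnz_per_gene)
  )
}

#' Median-depth normalization and log transform
#'
#' Scales every cell's counts so its total equals the median of the original
#' per-cell totals, then applies `log(1 + x)`. All-zero cells are dropped
#' with a warning.
#'
#' @param counts Genes x cells matrix (dense or `Matrix` sparse) with gene
#'   row names.
#' @return A list of class `norm_counts`: `x` (normalized, logged sparse
#'   matrix), `median_total`, `normalized = TRUE`, `log_transformed = TRUE`.
#' @export
normalize_and_log <- function(counts) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  totals <- Matrix::colSums(counts)
  if (all(totals == 0)) stop("all cells are empty", call. = FALSE)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " all-zero cell(s) dropped", call. = FALSE)
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  med <- stats::median(totals)
  scaled <- counts %*% Matrix::Diagonal(x = med / totals)
  dimnames(scaled) <- dimnames(counts)
  logged <- scaled
  logged@x <- log1p(logged@x)
  structure(
    list(x = logged, median_total = med,
         normalized = TRUE, log_transformed = TRUE),
    class = "norm_counts"
  )
}

resolve_gene <- function(x, gene) {
  rn <- rownames(x)
  hit <- which(rn == gene)
  if (length(hit) == 0L) hit <- which(tolower(rn) == tolower(gene))
  if (length(hit) == 0L) stop("gene not found: ", gene, call. = FALSE)
  hit[1]
}

#' Select the cells expressing a marker gene
#'
#' Retains cells whose normalized, log-transformed expression of `gene`
#' strictly exceeds `threshold` (default: Grpr > 0.01, the gate used to
#' define the population of interest). Gene symbols match exactly first, then
#' case-insensitively.
#'
#' @param norm A [normalize_and_log()] result.
#' @param gene Marker gene symbol.
#' @param threshold Expression threshold.
#' @param direction `">"` (default) or `"<"`.
#' @return A `norm_counts` restricted to the selected cells, with attribute
#'   `n_selected`; an empty selection is allowed but flagged with a warning.
#' @export
select_population <- function(norm, gene = "Grpr", threshold = 0.01,
                              direction = c(">", "<")) {
  stopifnot(inherits(norm, "norm_counts"))
  direction <- match.arg(direction)
  g <- resolve_gene(norm$x, gene)
  expr <- norm$x[g, ]
  keep <- if (direction == ">") expr > threshold else expr < threshold
  if (!any(keep)) warning("no cells selected for ", gene, call. = FALSE)
  out <- norm
  out$x <- norm$x[, keep, drop = FALSE]
  attr(out, "n_selected") <- sum(keep)
  out
}

#' Per-gene expression prevalence in a cell population
#'
#' For each panel gene, the percentage of cells whose normalized (logged)
#' expression strictly exceeds the threshold.
#'
#' @param norm A (typically population-selected) [normalize_and_log()] result.
#' @param panel Character vector of gene symbols.
#' @param threshold Expression threshold (default 0.01).
#' @param direction `">"` (default) or `"<"`.
#' @return A tibble: `gene`, `n_expressing`, `prevalence_percent`, plus the
#'   population size as attribute `population_size`.
#' @examples
#' sim <- gen_count_matrix(5, 200, prevalence = c(1, 0.9, 0.5, 0.1, 0))
#' nl <- normalize_and_log(sim$counts)
#' gene_prevalence(nl, c("gene1", "gene3"))
#' @export
gene_prevalence <- function(norm, panel, threshold = 0.01,
                            direction = c(">", "<")) {
  stopifnot(inherits(norm, "norm_counts"))
  direction <- match.arg(direction)
  if (length(panel) == 0L) stop("empty gene panel", call. = FALSE)
  n_cells <- ncol(norm$x)
  if (n_cells == 0L) stop("empty cell population", call. = FALSE)
  rows <- vapply(panel, resolve_gene, integer(1), x = norm$x)
  n_expr <- vapply(rows, function(g) {
    expr <- norm$x[g, ]
    if (direction == ">") sum(expr > threshold) else sum(expr < threshold)
  }, numeric(1))
  out <- tibble::tibble(
    gene = panel,
    n_expressing = as.integer(unname(n_expr)),
    prevalence_percent = 100 * unname(n_expr) / n_cells
  )
  attr(out, "population_size") <- n_cells
  out
}

#' Default marker and receptor-subunit panels
#'
#' Neuronal identity markers (vesicular transporters and transcription
#' factors) and the AMPA, GABA-A and glycine receptor subunit families
#' profiled in the population of interest.
#'
#' @return Named list of character vectors.
#' @export
default_panels <- function() {
  list(
    markers = c("Slc17a6", "Slc32a1", "Pax2", "Tlx3", "Ebf2"),
    ampa = paste0("Gria", 1:4),
    gabaa = paste0("Gabra", 1:6),
    glycine = c(paste0("Glra", 1:4), "Glrb")
  )
}

#' Read and write count matrices as MatrixMarket plus label files
#'
#' `write_count_matrix()` writes `<stem>.mtx` (genes x cells), `<stem>.genes.txt`
#' and `<stem>.cells.txt` (one label per line). `read_count_matrix()` reads
#' them back; it also accepts a delimited genes x cells table (`.tsv`/`.csv`
#' with gene names in the first column).
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param stem Path stem (no extension) for write; for read, the `.mtx` stem
#'   or a delimited file path.
#' @return `read_count_matrix()` returns a `dgCMatrix` with dimnames.
#' @export
write_count_matrix <- function(counts, stem) {
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".cells.txt"))
  invisible(stem)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(stem) {
  if (grepl("\\.(tsv|csv|txt)$", stem) && file.exists(stem)) {
    sep <- if (grepl("\\.csv$", stem)) "," else "\t"
    tab <- utils::read.table(stem, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE)
    return(methods::as(as.matrix(tab), "CsparseMatrix"))
  }
  mtx <- paste0(stem, ".mtx")
  if (!file.exists(mtx)) stop("no count matrix at ", stem, call. = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(paste0(stem, ".genes.txt"))
  cells <- readLines(paste0(stem, ".cells.txt"))
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop("label files do not match matrix dimensions", call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  m
}
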