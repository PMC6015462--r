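#' Validate an expression matrix
#'
#' Expression data are held as a plain numeric matrix, genes in rows and
#' samples in columns, with unique identifiers on both dimensions and no
#' missing values.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly unchanged, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("expression matrix needs gene rownames and sample colnames")
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup) > 0L) stopf("duplicate gene id '%s'", dup[1L])
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup) > 0L) stopf("duplicate sample id '%s'", dup[1L])
  if (ncol(x) < 3L) stopf("need at least 3 samples, got %d", ncol(x))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stopf("missing value at gene '%s', sample '%s'",
          rownames(x)[bad[1L]], colnames(x)[bad[2L]])
  }
  x
}

#' Read an expression matrix
#'
#' @param path file path.
#' @param dialect `"tsv"` (header of sample ids, first column gene ids) or
#'   `"gct"` (standard 1.2 layout: `#1.2` line, dimensions line, `Name` and
#'   `Description` columns; `Description` is ignored).
#' @param impute_missing if `TRUE`, missing cells are replaced by the row
#'   mean; the default is to reject files with missing values.
#' @return validated genes x samples numeric matrix.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   impute_missing = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  skip <- 0L
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L)
    if (!startsWith(head2[1L], "#1.2")) stopf("not a GCT 1.2 file: %s", path)
    skip <- 2L
  }
  df <- read.delim(path, header = TRUE, sep = "\t", skip = skip,
                   check.names = FALSE, colClasses = "character")
  gene_ids <- df[[1L]]
  if (dialect == "gct") df <- df[, -2L, drop = FALSE]  # drop Description
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) stopf("duplicate gene id '%s' in %s", dup[1L], path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad_cell <- is.na(num) & !is.na(vals) & !(vals %in% c("NA", "", "NaN"))
  if (any(bad_cell)) {
    idx <- which(bad_cell, arr.ind = TRUE)[1L, ]
    stopf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
          vals[idx[1L], idx[2L]], idx[1L], gene_ids[idx[1L]],
          colnames(vals)[idx[2L]])
  }
  mat <- matrix(num, nrow = length(gene_ids),
                dimnames = list(gene_ids, colnames(vals)))
  if (anyNA(mat)) {
    if (!impute_missing) {
      idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stopf("missing value at gene '%s', sample '%s' (set impute_missing = TRUE for row-mean imputation)",
            rownames(mat)[idx[1L]], colnames(mat)[idx[2L]])
    }
    for (i in which(rowSums(is.na(mat)) > 0L)) {
      mat[i, is.na(mat[i, ])] <- mean(mat[i, ], na.rm = TRUE)
    }
  }
  validate_expression_matrix(mat)
}

#' Write an expression matrix
#'
#' @param x validated expression matrix.
#' @param path destination path.
#' @param dialect `"tsv"` or `"gct"`.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  x <- validate_expression_matrix(x)
  con <- file(path, open = "wb")  # binary mode keeps LF endings everywhere
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x),
                     apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                                    collapse = "\t")),
                     sep = "\t"), con)
  } else {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), "na",
                     apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                                    collapse = "\t")),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Two tab-separated columns, `sample_id` and `group`, group labels `case` or
#' `control`.
#'
#' @param path file path.
#' @param expr optional expression matrix to cross-check sample coverage.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_phenotype <- function(path, expr = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  validate_phenotype(df, expr)
}

#' Validate a phenotype table
#' @param pheno data.frame with columns `sample_id`, `group`.
#' @inheritParams read_phenotype
#' @return the validated data.frame.
#' @export
validate_phenotype <- function(pheno, expr = NULL) {
  if (!all(c("sample_id", "group") %in% names(pheno))) {
    stopf("phenotype table needs columns 'sample_id' and 'group'")
  }
  bad <- setdiff(unique(pheno$group), c("case", "control"))
  if (length(bad) > 0L) stopf("unknown group label '%s'", bad[1L])
  if (!all(c("case", "control") %in% pheno$group)) {
    stopf("both case and control groups must be non-empty")
  }
  if (anyDuplicated(pheno$sample_id)) stopf("duplicate sample ids in phenotype")
  if (!is.null(expr)) {
    missing <- setdiff(pheno$sample_id, colnames(expr))
    if (length(missing) > 0L) {
      stopf("phenotype sample '%s' absent from expression matrix", missing[1L])
    }
  }
  pheno[, c("sample_id", "group")]
}

#' Write a phenotype table
#' @inheritParams validate_phenotype
#' @param path destination path.
#' @export
write_phenotype <- function(pheno, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\tgroup",
               paste(pheno$sample_id, pheno$group, sep = "\t")), con)
  invisible(path)
}

#' Read signed regulons from a GMT file
#'
#' Each TF occupies two GMT records, `<TF>|pos` and `<TF>|neg`, holding its
#' positive- and negative-mode targets. The GMT description field is
#' repurposed as a dialect extension: it stores the MI edge weights as
#' comma-separated reals aligned with the member columns (`"na"` when the
#' record is empty).
#'
#' @param path file path.
#' @return a `regulon_set`.
#' @export
read_regulon_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  ids <- vapply(recs, `[[`, character(1), 1L)
  if (!all(grepl("\\|(pos|neg)$", ids))) {
    stopf("GMT record '%s' lacks the |pos / |neg suffix",
          ids[!grepl("\\|(pos|neg)$", ids)][1L])
  }
  tf <- sub("\\|(pos|neg)$", "", ids)
  mode <- sub("^.*\\|", "", ids)
  parse_members <- function(r) {
    members <- if (length(r) > 2L) r[-(1:2)] else character(0)
    if (length(members) == 0L) return(numeric(0))
    w <- if (r[2L] == "na") rep(NA_real_, length(members)) else
      as.numeric(strsplit(r[2L], ",", fixed = TRUE)[[1L]])
    if (length(w) != length(members)) {
      stopf("weight count mismatch in GMT record '%s'", r[1L])
    }
    stats::setNames(w, members)
  }
  out <- list()
  for (u in unique(tf)) {
    ip <- which(tf == u & mode == "pos")
    ineg <- which(tf == u & mode == "neg")
    if (length(ip) != 1L || length(ineg) != 1L) {
      stopf("TF '%s' must have exactly one |pos and one |neg GMT record", u)
    }
    out[[u]] <- signed_regulon(u, pos = parse_members(recs[[ip]]),
                               neg = parse_members(recs[[ineg]]))
  }
  structure(out, class = "regulon_set")
}

#' Write signed regulons to a GMT file
#' @param regulons a `regulon_set`.
#' @param path destination path.
#' @export
write_regulon_gmt <- function(regulons, path) {
  fmt <- function(tf, mode, w) {
    desc <- if (length(w) == 0L) "na" else
      paste(format(w, trim = TRUE, digits = 15), collapse = ",")
    paste(c(paste0(tf, "|", mode), desc, names(w)), collapse = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in regulons) {
    writeLines(c(fmt(r$tf, "pos", r$pos), fmt(r$tf, "neg", r$neg)), con)
  }
  invisible(path)
}

#' Read a compound signature database
#'
#' Tab-separated, one row per treatment instance: `instance_id`, `compound`,
#' `cell_line`, then the full rank-ordered gene list (rank 1 = most
#' up-regulated). Every instance must list a permutation of the shared gene
#' universe. Instances are canonicalised by sorting on `instance_id`, so row
#' order in the file does not matter.
#'
#' @param path file path.
#' @return a `signature_db`: list with `universe` (character), `instances`
#'   (data.frame `instance_id`, `compound`, `cell_line`) and `ranks`
#'   (character matrix, one row per instance, ordered gene ids).
#' @export
read_signature_db <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (ncol(df) < 4L) stopf("signature DB needs metadata plus a gene list")
  meta <- df[, 1:3]
  names(meta) <- c("instance_id", "compound", "cell_line")
  ranks <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(ranks) <- list(meta$instance_id, NULL)
  signature_db(universe = sort(ranks[1L, ]), instances = meta, ranks = ranks)
}

#' Construct and validate a signature database
#' @param universe character vector: the shared gene universe.
#' @param instances data.frame with `instance_id`, `compound`, `cell_line`.
#' @param ranks character matrix of ordered gene ids, one row per instance.
#' @return a `signature_db` with instances sorted by id.
#' @export
signature_db <- function(universe, instances, ranks) {
  if (anyDuplicated(instances$instance_id)) stopf("duplicate instance ids")
  sorted_univ <- sort(unname(universe))
  for (i in seq_len(nrow(ranks))) {
    if (!identical(sort(unname(ranks[i, ])), sorted_univ)) {
      stopf("instance '%s' is not a permutation of the gene universe",
            instances$instance_id[i])
    }
  }
  ord <- order(instances$instance_id)
  structure(list(universe = sorted_univ,
                 instances = instances[ord, , drop = FALSE],
                 ranks = ranks[ord, , drop = FALSE]),
            class = "signature_db")
}

#' Write a compound signature database
#' @param db a `signature_db`.
#' @param path destination path.
#' @export
write_signature_db <- function(db, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("instance_id", "compound", "cell_line",
                     paste0("rank_", seq_along(db$universe))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(db$ranks))) {
    writeLines(paste(c(db$instances$instance_id[i], db$instances$compound[i],
                       db$instances$cell_line[i], db$ranks[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a generic results table as TSV
#' @param df data.frame.
#' @param path destination path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 15) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(c(paste(names(df), collapse = "\t"),
               apply(cells, 1L, paste, collapse = "\t")), con)
  invisible(path)
}
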