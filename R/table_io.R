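# ---- validators -----------------------------------------------------------

#' Validate a feature table
#'
#' A feature table is a samples x features matrix of non-negative integer
#' counts with unique, non-empty sample ids (rownames) and feature ids
#' (colnames).  This is the universal currency of the pipeline: rows are
#' samples, columns are ASVs or OTUs.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix (samples x features)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature table must carry sample ids (rownames) and feature ids (colnames)")
  dup_s <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_f))
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature table contains missing or non-finite counts")
  if (any(x < 0))
    stop("feature table contains negative counts")
  if (any(x != round(x)))
    stop("feature table contains non-integer counts")
  invisible(x)
}

#' Validate a distance matrix
#'
#' Accepts a `dist` object or a labelled square matrix; checks symmetry,
#' zero diagonal (hollowness), finiteness and non-negativity, and returns
#' the canonical `dist` representation.
#'
#' @param d `dist` or symmetric matrix.
#' @return a `dist` object with labels.
#' @export
validate_distance_matrix <- function(d) {
  if (inherits(d, "dist")) {
    v <- as.vector(d)
    if (anyNA(v) || any(!is.finite(v))) stop("distance matrix has non-finite entries")
    if (any(v < 0)) stop("distance matrix has negative entries")
    return(d)
  }
  if (!is.matrix(d)) stop("expected a dist object or a square matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distance matrix has negative entries")
  stats::as.dist(d)
}

compartment_levels <- c("BS", "LS", "TS")
env_variables <- c("soc", "ph", "no3_n", "nh4_n", "tn")

#' Validate sample metadata
#'
#' Metadata carries one row per sample with a `sample_id`, a soil
#' `compartment` (BS = bulk, LS = loosely bound, TS = tightly bound soil)
#' and optional soil-chemistry columns (`soc`, `ph`, `no3_n`, `nh4_n`,
#' `tn`).  Missing chemistry values stay `NA`; they are never imputed.
#'
#' @param md data.frame to validate.
#' @return `md`, invisibly.
#' @export
validate_metadata <- function(md) {
  if (!is.data.frame(md)) stop("metadata must be a data.frame")
  req <- c("sample_id", "compartment")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(as.character(md$compartment)), compartment_levels)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         "; admissible labels are ", paste(compartment_levels, collapse = ", "))
  for (v in intersect(env_variables, names(md))) {
    x <- md[[v]]
    if (!is.numeric(x)) stop("metadata column '", v, "' must be numeric")
    if (any(!is.na(x) & !is.finite(x))) stop("metadata column '", v, "' has non-finite values")
    if (v == "ph" && any(!is.na(x) & (x < 0 | x > 14))) stop("pH outside [0, 14]")
    if (v != "ph" && any(!is.na(x) & x < 0)) stop("metadata column '", v, "' must be >= 0")
  }
  invisible(md)
}

# ---- feature table I/O ----------------------------------------------------

#' Read a feature table
#'
#' @param path file path.
#' @param dialect `"tsv"` (samples as rows, first column = sample id) or
#'   `"biom-json"` (BIOM 1.0 dense JSON: rows are features, columns samples).
#'   The dialect is explicit, never sniffed.
#' @return validated integer matrix, samples x features.
#' @export
read_feature_table <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("empty feature table: ", path)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    feats <- header[-1L]
    body <- cells[-1L]
    samples <- vapply(body, `[[`, character(1L), 1L)
    counts <- matrix(NA_real_, length(body), length(feats),
                     dimnames = list(samples, feats))
    for (i in seq_along(body)) {
      row <- body[[i]]
      if (length(row) != length(feats) + 1L)
        stop("row ", i, " of ", path, " has ", length(row) - 1L,
             " cells, expected ", length(feats))
      vals <- suppressWarnings(as.numeric(row[-1L]))
      if (anyNA(vals)) {
        j <- which(is.na(vals))[1L]
        stop("non-numeric count at row ", i, " (sample ", samples[i],
             "), column ", j, " (feature ", feats[j], ")")
      }
      if (any(vals != round(vals))) {
        j <- which(vals != round(vals))[1L]
        stop("non-integer count at row ", i, ", column ", j)
      }
      if (any(vals < 0)) {
        j <- which(vals < 0)[1L]
        stop("negative count at row ", i, ", column ", j)
      }
      counts[i, ] <- vals
    }
    storage.mode(counts) <- "integer"
    validate_feature_table(counts)
    return(counts)
  }
  ## BIOM 1.0 dense JSON: rows = observations (features), columns = samples
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(b$matrix_type, "dense"))
    stop("only the BIOM 1.0 dense layout is supported (matrix_type = 'dense')")
  feats <- b$rows$id
  samples <- b$columns$id
  data <- b$data
  if (!is.matrix(data)) data <- matrix(data, nrow = length(feats), byrow = TRUE)
  counts <- t(data)
  dimnames(counts) <- list(samples, feats)
  if (any(counts != round(counts))) stop("non-integer count in BIOM data")
  storage.mode(counts) <- "integer"
  validate_feature_table(counts)
  counts
}

#' Write a feature table
#'
#' Outputs carry a header comment line with the package version and, when
#' given, the RNG seed that produced the table.
#'
#' @param x feature table (samples x features).
#' @param path output path.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @param seed optional seed recorded in the header comment (tsv) or
#'   comment field (biom-json).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, dialect = c("tsv", "biom-json"),
                                seed = NULL) {
  dialect <- match.arg(dialect)
  validate_feature_table(x)
  stamp <- paste0(pkg_version_string(),
                  if (!is.null(seed)) paste0("; seed=", seed))
  if (dialect == "tsv") {
    header <- paste(c("sample_id", colnames(x)), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(i)
      paste(c(rownames(x)[i], format(x[i, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t"), character(1L))
    writeLines(c(paste0("# ", stamp), header, rows), path)
  } else {
    b <- list(
      id = "feature-table",
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = pkg_version_string(),
      date = "1970-01-01T00:00:00",
      comment = stamp,
      matrix_type = "dense",
      matrix_element_type = "int",
      shape = c(ncol(x), nrow(x)),
      rows = lapply(colnames(x), function(id) list(id = id, metadata = NULL)),
      columns = lapply(rownames(x), function(id) list(id = id, metadata = NULL)),
      data = unname(lapply(seq_len(ncol(x)), function(j) unname(x[, j])))
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# ---- metadata I/O ---------------------------------------------------------

#' Read sample metadata
#'
#' Tab-separated with required columns `sample_id` and `compartment`;
#' chemistry columns are optional and missing values are kept as `NA`
#' (absent), never coerced to zero.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "compartment")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  md$compartment <- toupper(trimws(as.character(md$compartment)))
  validate_metadata(md)
  md
}

#' Write sample metadata
#' @param md metadata data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path, seed = NULL) {
  validate_metadata(md)
  stamp <- paste0(pkg_version_string(),
                  if (!is.null(seed)) paste0("; seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.table(md, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sequences and trees --------------------------------------------------

#' Read representative sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of DNA sequences over {A,C,G,T}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_repseqs(seqs)
  seqs
}

#' Write representative sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  validate_repseqs(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
validate_repseqs <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named by its feature id")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup)) stop("duplicated sequence id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence(s) present")
  if (any(grepl("[^ACGT]", seqs)))
    stop("sequences must be over the alphabet {A,C,G,T}")
  invisible(seqs)
}

#' Read a phylogenetic tree from Newick
#'
#' Unrooted trees are midpoint-rooted with a warning: UniFrac and Faith PD
#' need a root.  Negative branch lengths are rejected.
#'
#' @param path Newick file.
#' @return a rooted `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tr a `phylo` object.
#' @export
validate_tree <- function(tr) {
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicated tip label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length(s) in tree")
  if (!ape::is.rooted(tr)) {
    warning("input tree is unrooted; midpoint-rooting it")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Write a tree to Newick
#' @param tr a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

# ---- cross-validation -----------------------------------------------------

#' Cross-validate identifiers across pipeline artifacts
#'
#' Checks that the feature table's feature ids match the tree tips and the
#' representative-sequence ids, and that its sample ids match the metadata.
#' Every offending identifier is named in the error.
#'
#' @param table feature table.
#' @param tree optional `phylo`.
#' @param seqs optional named sequence vector.
#' @param metadata optional metadata data.frame.
#' @return `TRUE`, invisibly, when consistent.
#' @export
cross_validate <- function(table, tree = NULL, seqs = NULL, metadata = NULL) {
  validate_feature_table(table)
  problems <- character(0)
  chk <- function(a, b, what) {
    m1 <- setdiff(a, b); m2 <- setdiff(b, a)
    c(if (length(m1)) paste0(what, " missing: ", paste(m1, collapse = ", ")),
      if (length(m2)) paste0(what, " extra: ", paste(m2, collapse = ", ")))
  }
  if (!is.null(tree))
    problems <- c(problems, chk(colnames(table), tree$tip.label, "tree tip"))
  if (!is.null(seqs))
    problems <- c(problems, chk(colnames(table), names(seqs), "sequence id"))
  if (!is.null(metadata))
    problems <- c(problems, chk(rownames(table), metadata$sample_id, "metadata sample"))
  if (length(problems))
    stop("identifier cross-validation failed:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}
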