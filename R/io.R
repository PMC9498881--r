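#' Read an additive genotype matrix
#'
#' Supports two dialects: `"csv"` (first column is the subject id, one
#' column per SNP) and `"plink_raw"` (whitespace-separated with FID and
#' IID leading columns, in the style of PLINK `--recode A` output; any
#' PAT/MAT/SEX/PHENOTYPE bookkeeping columns are dropped and a trailing
#' counted-allele suffix such as `_A` is stripped from SNP names). Missing
#' dosages are preserved as `NA`. Any numeric value outside {0, 1, 2, NA}
#' is a format error reported with its row and column.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @return subjects x SNPs integer matrix with subject ids as rownames and
#'   SNP ids as colnames.
#' @export
read_genotypes <- function(path, dialect = c("csv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (dialect == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    dos <- tab[, -1, drop = FALSE]
  } else {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[["IID"]])
    drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      colnames(tab))
    dos <- tab[, setdiff(colnames(tab), drop), drop = FALSE]
    colnames(dos) <- sub("_[ACGT]$", "", colnames(dos))
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate subject ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(dos))) {
    stop("format error: duplicate SNP ids in ", path)
  }
  m <- as.matrix(dos)
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "format error: dosage %s not in {0,1,2} at subject '%s', SNP '%s'",
      format(m[bad[1, , drop = FALSE]]), ids[bad[1, 1]],
      colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a phenotype table with diagnosis, covariates and ROI traits
#'
#' Expects columns `subject_id`, `diagnosis`, `age`, `sex`, `education`,
#' followed by one numeric column per ROI quantitative trait. Subject
#' order is irrelevant downstream: genotype/phenotype alignment is always
#' by id. Duplicate subject ids or missing covariates are format errors.
#'
#' @param path CSV file path.
#' @return A data frame; ROI columns are every column after the covariate
#'   block. The ROI ids are attached as `attr(, "roi_ids")`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("subject_id", "diagnosis", "age", "sex", "education")
  missing_cols <- setdiff(req, colnames(tab))
  if (length(missing_cols) > 0) {
    stop("format error: phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("format error: duplicate subject ids: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  }
  incomplete <- tab$subject_id[!stats::complete.cases(
    tab[, c("age", "sex", "education")])]
  if (length(incomplete) > 0) {
    stop("format error: missing covariate values for subject(s): ",
         paste(incomplete, collapse = ", "))
  }
  roi_ids <- setdiff(colnames(tab), req)
  if (anyDuplicated(roi_ids)) stop("format error: duplicate ROI ids")
  attr(tab, "roi_ids") <- roi_ids
  tab
}

#' Define a case-control comparison cohort
#'
#' @param name short cohort label, e.g. `"AD_vs_HC"`.
#' @param case_labels,control_labels disjoint nonempty sets of diagnosis
#'   labels; the cohort used in regression is their union.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(name, case_labels, control_labels) {
  if (length(case_labels) == 0 || length(control_labels) == 0) {
    stop("case_labels and control_labels must both be nonempty")
  }
  if (length(intersect(case_labels, control_labels)) > 0) {
    stop("case_labels and control_labels must be disjoint")
  }
  structure(list(name = name, case_labels = case_labels,
                 control_labels = control_labels), class = "cohort_spec")
}

#' Write or read a labelled numeric matrix as TSV
#'
#' Matrices travel as tab-separated text with a header row and a leading
#' id column, written at full double precision so write-then-read is an
#' exact round trip. `kind = "network"` additionally enforces on read that
#' the matrix is square, symmetric, and has entries in [0, 1].
#'
#' @param m numeric matrix with dimnames (for `write_matrix`).
#' @param path file path.
#' @param kind `"association_map"` or `"network"`.
#' @return `read_matrix` returns the matrix (an association map carries
#'   its `normalized` attribute through the round trip via a header
#'   comment line).
#' @export
write_matrix <- function(m, path, kind = c("association_map", "network")) {
  kind <- match.arg(kind)
  if (kind == "network") {
    if (nrow(m) != ncol(m)) stop("network matrix must be square")
    if (max(abs(m - t(m))) > 1e-12) stop("network matrix must be symmetric")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (isTRUE(attr(m, "normalized"))) writeLines("# normalized: true", con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, kind = c("association_map", "network")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  normalized <- length(lines) > 0 && startsWith(lines[1], "# normalized:")
  if (normalized) lines <- lines[-1]
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  if (kind == "network") {
    if (nrow(m) != ncol(m)) stop("format error: network matrix must be square")
    if (max(abs(m - t(m))) > 1e-12) {
      stop("format error: network matrix is asymmetric")
    }
    if (min(m) < 0 || max(m) > 1) {
      stop("format error: network entries must lie in [0, 1]")
    }
    m
  } else {
    new_association_map(m, normalized = normalized)
  }
}

#' Read a SNP-to-gene annotation table
#'
#' Two-column TSV (snp id, gene symbol), e.g. each SNP mapped to its
#' closest gene upstream or downstream. Duplicate rows must agree; SNPs
#' absent from the table are simply unmapped (queries return `NA`), never
#' an error.
#'
#' @param path TSV path. A header line is detected and skipped if its
#'   first field is `snp_id`.
#' @return Named character vector mapping snp id to gene symbol.
#' @export
read_snp_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  if (length(readLines(path, n = 1)) == 0) return(stats::setNames(character(0), character(0)))
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           header = identical(first[1], "snp_id"))
  if (ncol(tab) < 2) stop("format error: gene map needs two columns")
  snp <- as.character(tab[[1]]); gene <- as.character(tab[[2]])
  dup <- duplicated(snp)
  if (any(dup)) {
    for (s in unique(snp[dup])) {
      if (length(unique(gene[snp == s])) > 1) {
        stop("format error: SNP '", s, "' maps to conflicting genes")
      }
    }
    gene <- gene[!dup]; snp <- snp[!dup]
  }
  stats::setNames(gene, snp)
}

#' Write or read a cluster assignment as JSON
#'
#' The on-disk schema is a JSON object `{snp_id: cluster_index}` with
#' 0-based cluster indices; in R the assignment is a named integer vector
#' with 1-based labels.
#'
#' @param assignment named integer vector of 1-based cluster labels.
#' @param path file path.
#' @export
write_assignment <- function(assignment, path) {
  obj <- as.list(as.integer(assignment) - 1L)
  names(obj) <- names(assignment)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  obj <- jsonlite::read_json(path)
  stats::setNames(vapply(obj, as.integer, integer(1)) + 1L, names(obj))
}
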