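# Readers/writers for the plain-text exchange formats used by the pipeline:
# quantification tables (TSV), sample designs (TSV), GMT gene sets and
# two-column paralog-pair tables. All quantification values are written with
# "%.17g" so that write -> read round-trips doubles exactly.

#' Read a protein quantification table
#'
#' Expects a tab-separated file with a header: a `protein_id` column, one
#' raw-area column per `sample_id` of the design, and optional
#' `<sample_id>.peptides` columns. Blank or missing numeric cells are read
#' as 0 ("not identified"). When no per-sample peptide columns are present,
#' a single `peptides` column (one count per protein, applied to all
#' samples) is accepted as a fallback.
#'
#' @param path file path.
#' @param design [sample_design()] declaring the expected sample columns.
#' @return a [quant_dataset()].
#' @export
read_quant_table <- function(path, design) {
  validate_design(design)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!"protein_id" %in% names(raw)) {
    stop("quantification table ", path, " lacks a 'protein_id' column")
  }
  missing <- setdiff(design$sample_id, names(raw))
  if (length(missing) > 0) {
    stop("quantification table ", path, " lacks sample column(s): ",
         paste(missing, collapse = ", "))
  }
  proteins <- raw$protein_id
  parse_col <- function(col) {
    v <- suppressWarnings(as.numeric(col))
    v[is.na(v) | col == ""] <- 0  # D-io-1: blank/NA encodes "not identified"
    v
  }
  read_matrix <- function(cols) {
    m <- matrix(0, nrow = length(proteins), ncol = length(cols))
    for (j in seq_along(cols)) m[, j] <- parse_col(raw[[cols[j]]])
    m
  }
  areas <- read_matrix(design$sample_id)
  dimnames(areas) <- list(proteins, design$sample_id)
  neg <- which(areas < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative area for protein ", proteins[neg[1, 1]], ", sample ",
         design$sample_id[neg[1, 2]], " in ", path)
  }
  pep_cols <- paste0(design$sample_id, ".peptides")
  if (all(pep_cols %in% names(raw))) {
    pc <- read_matrix(pep_cols)
  } else if ("peptides" %in% names(raw)) {
    # D-io-3 fallback: one per-protein count applied to every sample
    pc <- matrix(parse_col(raw$peptides), nrow = length(proteins),
                 ncol = nrow(design))
  } else {
    stop("quantification table ", path,
         " has neither per-sample '.peptides' columns nor a 'peptides' column")
  }
  quant_dataset(proteins, areas, pc, design)
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()]: writes `protein_id`, one area column per
#' sample and one `<sample_id>.peptides` column per sample. Zeros are
#' written as `0`, never as blanks, so the round trip is exact.
#'
#' @param dataset a [quant_dataset()].
#' @param path output file path.
#' @export
write_quant_table <- function(dataset, path) {
  validate_quant_dataset(dataset)
  fmt <- function(m) apply(m, 2, function(col) sprintf("%.17g", col))
  n <- length(dataset$proteins)
  areas <- matrix(fmt(dataset$areas), nrow = n)
  peps <- matrix(sprintf("%d", as.integer(dataset$peptide_counts)), nrow = n)
  out <- cbind(dataset$proteins, areas, peps)
  header <- c("protein_id", dataset$design$sample_id,
              paste0(dataset$design$sample_id, ".peptides"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (n > 0) {
    writeLines(apply(out, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `condition`, `assay`, `replicate`,
#' `method`.
#' @param path file path.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("sample_id", "condition", "assay", "replicate", "method")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("design file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  sample_design(d$sample_id, d$condition, d$assay, d$replicate, d$method)
}

#' Write a sample design table
#' @param design a [sample_design()].
#' @param path output file path.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then zero or more member IDs, all
#' tab-separated. Duplicate members within a line are dropped with a
#' warning.
#'
#' @param path file path.
#' @return a `gene_set_collection`: list with `sets` (named list of
#'   `list(description, members)`) and `background` (NULL unless set later).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("GMT line ", i, " has fewer than 2 fields in ", path)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (set '", fields[1],
              "'): duplicate members dropped")
      members <- unique(members)
    }
    sets[[fields[1]]] <- list(description = fields[2], members = members)
  }
  structure(list(sets = sets, background = NULL),
            class = "gene_set_collection")
}

#' Build a gene-set collection in code
#' @param sets named list of character vectors (members per set).
#' @param descriptions optional character vector parallel to `sets`.
#' @param background optional character vector of universe IDs.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                background = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  out <- mapply(function(m, d) list(description = d, members = unique(m)),
                sets, descriptions, SIMPLIFY = FALSE)
  structure(list(sets = out, background = background),
            class = "gene_set_collection")
}

#' Read a paralog-pair table
#'
#' Two-column TSV, one unordered pair per line. Duplicate pairs (in either
#' order) are collapsed with a warning; self-pairs and proteins occurring in
#' more than one pair are errors, since the input is expected to be a
#' pairing (e.g. 547 disjoint pairs covering 1,094 proteins).
#'
#' @param path file path.
#' @param header does the file carry a header line? Default FALSE.
#' @return a `paralog_table`: data.frame with columns `a`, `b`.
#' @export
read_paralog_pairs <- function(path, header = FALSE) {
  d <- utils::read.delim(path, header = header, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) != 2) stop("paralog-pair file ", path, " must have 2 columns")
  paralog_table(d[[1]], d[[2]])
}

#' Construct a paralog-pair table
#' @param a,b character vectors: the two members of each pair.
#' @export
paralog_table <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) {
    stop("self-pair(s): ", paste(unique(a[a == b]), collapse = ", "))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate paralog pair(s) collapsed: ",
            paste(unique(paste(lo, hi)[duplicated(key)]), collapse = ", "))
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
  }
  members <- c(lo, hi)
  if (anyDuplicated(members)) {
    stop("protein(s) occurring in more than one pair: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  structure(data.frame(a = lo, b = hi, stringsAsFactors = FALSE),
            class = c("paralog_table", "data.frame"))
}
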