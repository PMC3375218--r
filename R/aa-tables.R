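# Amino-acid bookkeeping shared across the package.  The canonical residue
# order everywhere (tables, the 20x20 matrix, integer codes) is alphabetical
# one-letter code: A C D E F G H I K L M N P Q R S T V W Y.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS", "LEU",
         "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL", "TRP", "TYR")

#' Convert residue names between three-letter and one-letter codes
#'
#' @param x character vector of residue codes.
#' @return character vector of the converted codes.
#' @keywords internal
aa_3to1 <- function(x) {
  i <- match(toupper(x), AA3)
  if (anyNA(i)) stop("unknown residue type(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  AA1[i]
}

aa_1to3 <- function(x) {
  i <- match(toupper(x), AA1)
  if (anyNA(i)) stop("unknown residue code(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  AA3[i]
}

# 0-based integer codes used by the compiled backend
aa_index <- function(x) {
  x <- toupper(x)
  i <- if (all(nchar(x) == 1)) match(x, AA1) else match(x, AA3)
  if (anyNA(i)) stop("unknown residue type(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  i - 1L
}

kf_extdata <- function(file) {
  path <- system.file("extdata", file, package = "knotfold")
  if (!nzchar(path)) stop("missing data asset: ", file)
  path
}

#' Read a whitespace-delimited 20x20 quasi-chemical contact matrix
#'
#' The expected layout is one header row and one header column of residue
#' one-letter codes.  The shipped default
#' (`qc_contact_potential_synthetic.tsv`) is a synthetic Miyazawa--Jernigan
#' style table constructed from per-residue contact propensities with an
#' arithmetic-mean combining rule; any table in the same layout can be
#' supplied instead.
#'
#' @param path path to the table; default is the shipped synthetic matrix.
#' @return symmetric 20x20 numeric matrix with residue one-letter dimnames.
#' @export
read_qc_matrix <- function(path = kf_extdata("qc_contact_potential_synthetic.tsv")) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  if (!identical(dim(m), c(20L, 20L)))
    stop("quasi-chemical matrix must be 20x20")
  m <- m[AA1, AA1]
  if (max(abs(m - t(m))) > 1e-9) stop("quasi-chemical matrix must be symmetric")
  m
}

# two-column residue tables (code, value)
read_residue_table <- function(path, what) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  v <- d[[2]][match(AA1, d[[1]])]
  if (anyNA(v)) stop("missing table entry in ", what, " for: ",
                     paste(AA1[is.na(v)], collapse = ", "))
  names(v) <- AA1
  v
}
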