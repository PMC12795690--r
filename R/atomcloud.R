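#' Chemical element vocabulary of the point-cloud featurisation
#'
#' The 22 element symbols recognised by the chemical one-hot encoding.
#' Atoms whose element is outside this vocabulary are dropped at parse time
#' (the count is recorded on the returned [atom_cloud()]).
#'
#' @return Character vector of length 22.
#' @export
element_vocabulary <- function() {
  c("H", "Li", "C", "N", "O", "Na", "Mg", "P", "S", "K", "Ca",
    "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Sr", "Cd", "Cs", "Hg")
}

# van der Waals-ish radii (Angstrom) used by the surface sampler; values for
# the metals are coarse but only matter when such atoms are present.
default_atom_radii <- function() {
  c(H = 1.10, Li = 1.82, C = 1.70, N = 1.55, O = 1.52, Na = 2.27,
    Mg = 1.73, P = 1.80, S = 1.80, K = 2.75, Ca = 2.31, Mn = 2.05,
    Fe = 2.05, Co = 2.00, Ni = 1.97, Cu = 1.96, Zn = 2.01, Se = 1.90,
    Sr = 2.49, Cd = 2.18, Cs = 3.43, Hg = 2.09)
}

canonical_element <- function(x) {
  x <- trimws(as.character(x))
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  x
}

#' Construct an atom cloud
#'
#' An atom cloud is the raw structural input of the pipeline: atomic
#' coordinates with element symbols, chain identifiers and residue indices.
#' Out-of-vocabulary elements (see [element_vocabulary()]) are removed and
#' counted; every retained chain must keep at least 4 atoms.
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param elements Character vector of element symbols (any letter case).
#' @param chain_id Character vector of per-atom chain identifiers.
#' @param residue_index Integer vector of per-atom residue numbers.
#' @return An object of class `atom_cloud`: a list with fields `coords`,
#'   `elements`, `chain_id`, `residue_index`, and attribute `dropped`
#'   (number of out-of-vocabulary atoms removed).
#' @export
atom_cloud <- function(coords, elements, chain_id, residue_index) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  n <- nrow(coords)
  elements <- canonical_element(elements)
  chain_id <- as.character(chain_id)
  residue_index <- as.integer(residue_index)
  if (length(elements) != n || length(chain_id) != n ||
      length(residue_index) != n)
    stop("coords, elements, chain_id and residue_index lengths differ")
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")

  keep <- elements %in% element_vocabulary()
  dropped <- sum(!keep)
  coords <- coords[keep, , drop = FALSE]
  elements <- elements[keep]
  chain_id <- chain_id[keep]
  residue_index <- residue_index[keep]
  if (nrow(coords) == 0)
    stop_ptppi("ptppi_degenerate_chain", "no atoms left after element filtering")
  structure(list(coords = coords, elements = elements, chain_id = chain_id,
                 residue_index = residue_index),
            dropped = dropped, class = "atom_cloud")
}

#' @export
print.atom_cloud <- function(x, ...) {
  cat(sprintf("<atom_cloud> %d atoms, %d chain(s) [%s], %d dropped\n",
              nrow(x$coords), length(unique(x$chain_id)),
              paste(unique(x$chain_id), collapse = ","),
              attr(x, "dropped") %||% 0L))
  invisible(x)
}

#' Read a protein structure into an atom cloud
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}), keeps standard `ATOM`
#' records (heteroatoms and waters excluded), drops out-of-vocabulary
#' elements with a recorded count, and returns one [atom_cloud()] for the
#' whole file with chain labels preserved.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param min_atoms_per_chain If any chain retains fewer atoms than this, a
#'   degenerate-chain error naming the chain is raised. The default (1)
#'   accepts any parseable chain; surface sampling and graph construction
#'   need at least 4 atoms, so pipelines typically set this to 4.
#' @return An [atom_cloud()].
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"),
                           min_atoms_per_chain = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ptppi("ptppi_format_error",
                                     sprintf("file not found: %s", path))
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop_ptppi("ptppi_format_error",
      sprintf("could not parse %s as %s: %s", path, format, conditionMessage(e))))
  at <- parsed$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0) stop_ptppi("ptppi_format_error",
                                sprintf("no ATOM records in %s", path))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    # fall back to first letter of the atom name
    elem <- substr(trimws(at$elety), 1, 1)
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  cloud <- atom_cloud(cbind(at$x, at$y, at$z), elem, chain, at$resno)
  if (min_atoms_per_chain > 1) {
    cnt <- table(cloud$chain_id)
    bad <- names(cnt)[cnt < min_atoms_per_chain]
    if (length(bad))
      stop_ptppi("ptppi_degenerate_chain",
                 sprintf("chain(s) %s retain fewer than %d atoms",
                         paste(bad, collapse = ","), min_atoms_per_chain))
  }
  cloud
}

#' Split an atom cloud by chain
#'
#' @param cloud An [atom_cloud()].
#' @return Named list of single-chain `atom_cloud` objects.
#' @export
split_chains <- function(cloud) {
  out <- list()
  for (ch in unique(cloud$chain_id)) {
    i <- cloud$chain_id == ch
    out[[ch]] <- atom_cloud(cloud$coords[i, , drop = FALSE],
                            cloud$elements[i], cloud$chain_id[i],
                            cloud$residue_index[i])
  }
  out
}

#' Write / read the tabular atom-cloud dump
#'
#' Plain tab-separated serialisation (`x y z element chain residue`) that
#' round-trips an [atom_cloud()] exactly.
#'
#' @param cloud An [atom_cloud()].
#' @param path Output/input file path.
#' @return `write_atom_cloud()` returns `path` invisibly;
#'   `read_atom_cloud()` returns an [atom_cloud()].
#' @export
write_atom_cloud <- function(cloud, path) {
  df <- data.frame(x = cloud$coords[, 1], y = cloud$coords[, 2],
                   z = cloud$coords[, 3], element = cloud$elements,
                   chain = cloud$chain_id, residue = cloud$residue_index)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atom_cloud
#' @export
read_atom_cloud <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("numeric", "numeric", "numeric",
                                  "character", "character", "integer"))
  atom_cloud(cbind(df$x, df$y, df$z), df$element, df$chain, df$residue)
}
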