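#' Construct a molecule
#'
#' A `molecule` is an ordered set of atoms: element symbols, free-form
#' site labels and Cartesian coordinates in Angstrom.  Atom order is
#' meaningful throughout the package: shape distances assume a shared
#' ordering between conformers (see [match_atoms()]).
#'
#' @param coords numeric k x 3 matrix of coordinates (Angstrom).
#' @param elements character vector of IUPAC element symbols, length k.
#' @param labels optional character vector of site labels (defaults to
#'   `element` + ordinal, e.g. `"C1"`, `"H2"`).
#' @param name molecule name.
#' @param provenance optional list describing the source (path, format,
#'   raw records for PDBQT round-trips).
#' @return An object of class `molecule` with fields `name`, `elements`,
#'   `labels`, `coords`, `provenance`.
#' @examples
#' m <- molecule(rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               c("O", "H", "H"), name = "water")
#' n_atoms(m)
#' @export
molecule <- function(coords, elements, labels = NULL, name = "molecule",
                     provenance = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("`coords` must be a k x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  elements <- as.character(elements)
  if (length(elements) != nrow(coords))
    stop("`elements` length must equal nrow(coords)", call. = FALSE)
  bad <- setdiff(unique(elements), .ELEMENTS)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(labels))
    labels <- paste0(elements, seq_along(elements))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(name = name, elements = elements,
                 labels = as.character(labels), coords = coords,
                 provenance = provenance),
            class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  nrow(mol$coords)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%s)\n", x$name, n_atoms(x),
              paste(sprintf("%s:%d", names(table(x$elements)),
                            as.integer(table(x$elements))),
                    collapse = " ")))
  invisible(x)
}

#' Apply a rigid (or similarity) transform to a molecule
#'
#' Coordinates become `scale * coords %*% t(rotation) + translation`.
#' Used mainly by the tests and the ligand-frame module.
#'
#' @param mol a [molecule()].
#' @param rotation 3 x 3 orthogonal matrix.
#' @param translation length-3 numeric.
#' @param scale positive scalar.
#' @return the transformed molecule.
#' @export
transform_molecule <- function(mol, rotation = diag(3),
                               translation = c(0, 0, 0), scale = 1) {
  stopifnot(inherits(mol, "molecule"), scale > 0)
  xy <- scale * mol$coords %*% t(rotation)
  xy <- sweep(xy, 2, translation, "+")
  out <- mol
  out$coords <- xy
  dimnames(out$coords) <- list(NULL, c("x", "y", "z"))
  out
}
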