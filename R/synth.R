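#' Random synthetic molecule
#'
#' Test scaffold: coordinates uniform in a 10-Angstrom cube,
#' deterministic under `seed`, elements assigned in the order given.
#' Not chemically realistic and not meant to be.
#'
#' @param k atom count (k >= 4).
#' @param elements character vector recycled to length `k` (default a
#'   C/O/H mixture, so element subspaces are populated).
#' @param seed integer seed.
#' @param name molecule name.
#' @return a [molecule()].
#' @export
random_molecule <- function(k, elements = c("C", "O", "H"), seed = 1L,
                            name = sprintf("synthetic_%d", seed)) {
  stopifnot(k >= 4L)
  elements <- rep_len(elements, k)
  coords <- with_seed(seed, matrix(stats::runif(3L * k, 0, 10), k, 3L))
  molecule(coords, elements, name = name)
}

#' Synthetic parent/anion geometry pair
#'
#' Emulates the geometric relation between an optimized parent and its
#' deprotonated anion: one hydrogen deleted, every remaining atom
#' perturbed by an isotropic Gaussian of standard deviation `sigma`
#' (per coordinate, Angstrom).  With `sigma = 0` the matched-atom shape
#' distance is exactly 0; it grows with `sigma` in expectation.
#'
#' @param parent a [molecule()].
#' @param site_hydrogen index of the hydrogen to delete (must be H).
#' @param sigma Gaussian sigma in Angstrom (>= 0).
#' @param seed integer seed.
#' @return list with `variant` (a [molecule()]) and `map` (the
#'   ground-truth `atom_map`; the deleted parent hydrogen is the single
#'   unmatched parent atom).
#' @export
make_anion_pair <- function(parent, site_hydrogen, sigma = 0.02,
                            seed = 1L) {
  stopifnot(inherits(parent, "molecule"), sigma >= 0)
  k <- n_atoms(parent)
  i <- as.integer(site_hydrogen)
  if (i < 1L || i > k || parent$elements[i] != "H")
    stop("site_hydrogen must index a hydrogen atom of the parent",
         call. = FALSE)
  keep <- setdiff(seq_len(k), i)
  coords <- parent$coords[keep, , drop = FALSE]
  if (sigma > 0)
    coords <- coords + with_seed(seed,
      matrix(stats::rnorm(length(coords), 0, sigma), nrow(coords), 3L))
  variant <- molecule(coords, parent$elements[keep],
                      labels = parent$labels[keep],
                      name = paste0(parent$name, "_anion"))
  map <- .atom_map(cbind(keep, seq_along(keep)), i, integer(0))
  list(variant = variant, map = map)
}

#' Species enthalpies realizing chosen descriptor targets
#'
#' Inverse construction: given per-site target (BDE, PA) values and a
#' compound IP, builds a species-enthalpy table such that
#' [compute_descriptors()] recovers the targets exactly; ETE and PDE
#' then follow from the thermodynamic-cycle identities
#' ETE = BDE - PA + delta' and PDE = BDE - IP + delta' with
#' delta' = H(H+) + H(e-) - H(H.).
#'
#' @param targets data.frame with columns `site`, `BDE`, `PA`
#'   (kcal/mol).
#' @param IP target ionization potential (kcal/mol).
#' @param ref a [reference_enthalpies()].
#' @param base_H enthalpy assigned to the parent species (kcal/mol);
#'   arbitrary, descriptors are differences.
#' @param compound compound name.
#' @return data.frame of species enthalpies (columns `compound`, `site`,
#'   `role`, `H`, `unit`).
#' @export
synth_enthalpy_table <- function(targets, IP, ref = reference_enthalpies(),
                                 base_H = 0, compound = "synthetic") {
  targets <- as.data.frame(targets)
  stopifnot(all(c("site", "BDE", "PA") %in% names(targets)),
            all(is.finite(targets$BDE)), all(is.finite(targets$PA)),
            is.finite(IP))
  H_par <- base_H
  rows <- list(data.frame(compound = compound, site = "parent",
                          role = "parent", H = H_par,
                          stringsAsFactors = FALSE),
               data.frame(compound = compound, site = "parent",
                          role = "cation_radical",
                          H = IP + H_par - ref$H_electron,
                          stringsAsFactors = FALSE))
  for (r in seq_len(nrow(targets))) {
    s <- targets$site[r]
    rows[[length(rows) + 1L]] <-
      data.frame(compound = compound, site = s, role = "radical",
                 H = targets$BDE[r] + H_par - ref$H_hydrogen_atom,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(compound = compound, site = s, role = "anion",
                 H = targets$PA[r] + H_par - ref$H_proton,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$unit <- "kcal/mol"
  out
}
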