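#' Read a molecular coordinate file
#'
#' Supported formats: XYZ, PDB (fixed-column ATOM/HETATM records),
#' SDF (V2000 counts + atom block) and PDBQT.  Coordinates are taken to
#' be in Angstrom.  For PDBQT every input line is retained in the
#' molecule's provenance so that [write_structure()] can rewrite only the
#' coordinate fields and leave AutoDock atom types, charges and torsion
#'-tree records untouched.
#'
#' @param path file path.
#' @param format one of `"xyz"`, `"pdb"`, `"sdf"`, `"pdbqt"`; guessed
#'   from the file extension when omitted.
#' @return a [molecule()].
#' @seealso [write_structure()], [match_atoms()]
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  format <- tolower(format %||% tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb", "sdf", "pdbqt"))
  lines <- readLines(path, warn = FALSE)
  mol <- switch(format,
                xyz   = .read_xyz(lines, path),
                pdb   = .read_pdb(lines, path, pdbqt = FALSE),
                pdbqt = .read_pdb(lines, path, pdbqt = TRUE),
                sdf   = .read_sdf(lines, path))
  mol$provenance$path <- path
  mol$provenance$format <- format
  mol
}

.parse_error <- function(path, lineno, what) {
  stop(sprintf("parse error in '%s' line %d: %s", path, lineno, what),
       call. = FALSE)
}

.check_element <- function(el, path, lineno) {
  if (!el %in% .ELEMENTS)
    .parse_error(path, lineno, paste0("unknown element '", el, "'"))
  el
}

.read_xyz <- function(lines, path) {
  if (!length(lines)) .parse_error(path, 1L, "empty file")
  k <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(k) || k < 1L)
    .parse_error(path, 1L, "expected atom count header")
  if (length(lines) < k + 2L)
    .parse_error(path, length(lines), "truncated atom block")
  el <- character(k); xyz <- matrix(NA_real_, k, 3L)
  for (i in seq_len(k)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      .parse_error(path, ln, "expected 'element x y z'")
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      .parse_error(path, ln, "non-numeric coordinate")
    el[i] <- .check_element(tok[1L], path, ln)
    xyz[i, ] <- v
  }
  molecule(xyz, el, name = trimws(lines[2L]))
}

# AutoDock atom types -> element symbols (coordinate-level subset).
.ADTYPE_MAP <- c(A = "C", NA_ = "N", OA = "O", SA = "S", HD = "H",
                 HS = "H", NS = "N", OS = "O", CL = "Cl", BR = "Br",
                 FE = "Fe", MG = "Mg", MN = "Mn", ZN = "Zn", CA = "Ca")

.element_from_name <- function(name, path, lineno) {
  # PDB atom-name heuristic: strip digits/primes, try two-letter symbol
  # (columns 13-14) then one-letter.
  alpha <- gsub("[^A-Za-z]", "", name)
  if (!nchar(alpha)) .parse_error(path, lineno, "cannot infer element")
  two <- paste0(toupper(substr(alpha, 1, 1)),
                tolower(substr(alpha, 2, 2)))
  if (nchar(alpha) >= 2 && two %in% .ELEMENTS && !two %in% c("Cd", "Nd",
      "Ca", "Cs", "Ho", "Os", "Hs", "Np"))
    return(two)
  one <- toupper(substr(alpha, 1, 1))
  if (one %in% .ELEMENTS) return(one)
  .parse_error(path, lineno, paste0("cannot infer element from '",
                                    name, "'"))
}

.read_pdb <- function(lines, path, pdbqt = FALSE) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (!length(idx)) .parse_error(path, 1L, "no ATOM/HETATM records")
  k <- length(idx)
  el <- character(k); lab <- character(k); xyz <- matrix(NA_real_, k, 3L)
  for (i in seq_len(k)) {
    ln <- idx[i]; line <- lines[ln]
    if (nchar(line) < 54L)
      .parse_error(path, ln, "ATOM record shorter than 54 columns")
    xyz[i, ] <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                              substr(line, 39, 46),
                                              substr(line, 47, 54))))
    if (any(is.na(xyz[i, ])))
      .parse_error(path, ln, "non-numeric coordinate field")
    name <- trimws(substr(line, 13, 16))
    lab[i] <- if (nchar(name)) name else paste0("X", i)
    if (pdbqt) {
      type <- trimws(substr(line, 78, 79))
      key <- if (type == "NA") "NA_" else toupper(type)
      el[i] <- if (key %in% names(.ADTYPE_MAP)) {
        .ADTYPE_MAP[[key]]
      } else if (type %in% .ELEMENTS) {
        type
      } else {
        .element_from_name(name, path, ln)
      }
    } else {
      esym <- trimws(substr(line, 77, 78))
      esym <- paste0(toupper(substr(esym, 1, 1)), tolower(substr(esym, 2, 2)))
      el[i] <- if (nchar(esym) && esym %in% .ELEMENTS) esym else
        .element_from_name(name, path, ln)
    }
  }
  prov <- list(raw_lines = lines, atom_line_idx = idx)
  molecule(xyz, el, labels = lab,
           name = tools::file_path_sans_ext(basename(path)),
           provenance = prov)
}

.read_sdf <- function(lines, path) {
  if (length(lines) < 4L) .parse_error(path, length(lines), "truncated header")
  k <- suppressWarnings(as.integer(substr(lines[4L], 1, 3)))
  if (is.na(k) || k < 1L)
    .parse_error(path, 4L, "bad counts line")
  if (!grepl("V2000", lines[4L]))
    .parse_error(path, 4L, "only V2000 connection tables are supported")
  if (length(lines) < 4L + k)
    .parse_error(path, length(lines), "truncated atom block")
  el <- character(k); xyz <- matrix(NA_real_, k, 3L)
  for (i in seq_len(k)) {
    ln <- 4L + i; line <- lines[ln]
    xyz[i, ] <- suppressWarnings(as.numeric(c(substr(line, 1, 10),
                                              substr(line, 11, 20),
                                              substr(line, 21, 30))))
    if (any(is.na(xyz[i, ])))
      .parse_error(path, ln, "non-numeric coordinate field")
    el[i] <- .check_element(trimws(substr(line, 32, 34)), path, ln)
  }
  molecule(xyz, el, name = trimws(lines[1L]))
}

#' Write a molecular coordinate file
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @param format `"xyz"`, `"pdb"`, `"sdf"` or `"pdbqt"`; guessed from the
#'   extension when omitted.  `"pdbqt"` requires that `mol` was read from
#'   a PDBQT file (its provenance carries the non-coordinate columns);
#'   only the x/y/z fields are rewritten, everything else round-trips
#'   byte-identically.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = NULL) {
  stopifnot(inherits(mol, "molecule"))
  format <- tolower(format %||% tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb", "sdf", "pdbqt"))
  lines <- switch(format,
                  xyz = .write_xyz(mol),
                  pdb = .write_pdb(mol),
                  sdf = .write_sdf(mol),
                  pdbqt = .write_pdbqt(mol))
  writeLines(lines, path)
  invisible(path)
}

.write_xyz <- function(mol) {
  c(sprintf("%d", n_atoms(mol)), mol$name,
    sprintf("%-2s %15.8f %15.8f %15.8f", mol$elements,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
}

.write_pdb <- function(mol) {
  k <- n_atoms(mol)
  name4 <- ifelse(nchar(mol$elements) == 1L,
                  sprintf(" %-3s", substr(mol$labels, 1, 3)),
                  sprintf("%-4s", substr(mol$labels, 1, 4)))
  rec <- sprintf(
    "HETATM%5d %s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(k), name4, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3],
    mol$elements)
  c(rec, "END")
}

.write_sdf <- function(mol) {
  k <- n_atoms(mol)
  c(mol$name, "  betashape         3D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", k, 0L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3],
            mol$elements),
    "M  END", "$$$$")
}

.write_pdbqt <- function(mol) {
  prov <- mol$provenance
  if (is.null(prov$raw_lines) || is.null(prov$atom_line_idx))
    stop("PDBQT output requires a molecule read from PDBQT ",
         "(non-coordinate columns are preserved from the source)",
         call. = FALSE)
  idx <- prov$atom_line_idx
  if (length(idx) != n_atoms(mol))
    stop("provenance atom records do not match atom count", call. = FALSE)
  lines <- prov$raw_lines
  coords <- sprintf("%8.3f%8.3f%8.3f", mol$coords[, 1], mol$coords[, 2],
                    mol$coords[, 3])
  for (i in seq_along(idx)) {
    ln <- lines[idx[i]]
    lines[idx[i]] <- paste0(substr(ln, 1, 30), coords[i],
                            substr(ln, 55, nchar(ln)))
  }
  lines
}

#' Establish atom correspondence between a parent and a variant
#'
#' The default rule mirrors how deprotonated conformers are usually
#' produced from an optimized parent: atom ordering is shared except
#' that the variant may lack exactly one hydrogen.  If the sizes differ
#' by one, every deletion position consistent with the shared ordering
#' is enumerated; `removed_label` (a heavy-atom site label such as
#' `"C17"`) disambiguates by choosing the candidate hydrogen closest to
#' that heavy atom in the parent, otherwise the earliest consistent
#' deletion is used.
#'
#' Indices are 1-based (R convention).  An explicit map read with
#' [read_atom_map()] overrides the heuristic entirely.
#'
#' @param parent,variant [molecule()] objects.
#' @param removed_label optional heavy-atom site label naming the
#'   deprotonation site.
#' @return an object of class `atom_map`: list with `pairs` (m x 2
#'   integer matrix, columns = index in parent / index in variant),
#'   `unmatched_A`, `unmatched_B`.
#' @export
match_atoms <- function(parent, variant, removed_label = NULL) {
  stopifnot(inherits(parent, "molecule"), inherits(variant, "molecule"))
  kA <- n_atoms(parent); kB <- n_atoms(variant)
  if (kB > kA || kA - kB > 1L)
    stop("variant must have k or k-1 atoms (parent k = ", kA,
         ", variant k = ", kB, ")", call. = FALSE)
  if (kA == kB) {
    if (!identical(parent$elements, variant$elements))
      stop("element mismatch along the shared ordering; supply an ",
           "explicit atom map", call. = FALSE)
    return(.atom_map(cbind(seq_len(kA), seq_len(kA)),
                     integer(0), integer(0)))
  }
  # one deletion: enumerate hydrogens whose removal reconciles orderings
  cand <- which(parent$elements == "H")
  cand <- cand[vapply(cand, function(d)
    identical(parent$elements[-d], variant$elements), logical(1))]
  if (!length(cand))
    stop("no single hydrogen deletion reconciles the two orderings; ",
         "supply an explicit atom map", call. = FALSE)
  d <- cand[1L]
  if (!is.null(removed_label)) {
    heavy <- which(parent$labels == removed_label)
    if (length(heavy) != 1L)
      stop("removed_label '", removed_label,
           "' does not name a unique parent atom", call. = FALSE)
    dd <- sqrt(rowSums((parent$coords[cand, , drop = FALSE] -
                          matrix(parent$coords[heavy, ], length(cand), 3,
                                 byrow = TRUE))^2))
    d <- cand[which.min(dd)]
  }
  .atom_map(cbind(setdiff(seq_len(kA), d), seq_len(kB)), d, integer(0))
}

.atom_map <- function(pairs, unmatched_A, unmatched_B) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("A", "B")))
  structure(list(pairs = pairs, unmatched_A = as.integer(unmatched_A),
                 unmatched_B = as.integer(unmatched_B)),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map> %d pairs; unmatched A: %s; unmatched B: %s\n",
              nrow(x$pairs),
              if (length(x$unmatched_A))
                paste(x$unmatched_A, collapse = ",") else "-",
              if (length(x$unmatched_B))
                paste(x$unmatched_B, collapse = ",") else "-"))
  invisible(x)
}

#' Read an explicit atom map from a file
#'
#' Whitespace-delimited integer pairs, one matched pair per line.
#' Indices in the file are 0-based (the cross-tool convention);
#' they are converted to R's 1-based indexing on read.
#'
#' @param path file path.
#' @param parent,variant optional molecules used to validate the map
#'   (element agreement on every pair, injectivity).
#' @return an `atom_map`.
#' @export
read_atom_map <- function(path, parent = NULL, variant = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, col.names = c("A", "B"))
  pairs <- as.matrix(tab) + 1L
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("atom map is not injective", call. = FALSE)
  ua <- integer(0); ub <- integer(0)
  if (!is.null(parent)) {
    if (any(pairs[, 1] < 1L | pairs[, 1] > n_atoms(parent)))
      stop("map index out of range for parent", call. = FALSE)
    ua <- setdiff(seq_len(n_atoms(parent)), pairs[, 1])
  }
  if (!is.null(variant)) {
    if (any(pairs[, 2] < 1L | pairs[, 2] > n_atoms(variant)))
      stop("map index out of range for variant", call. = FALSE)
    ub <- setdiff(seq_len(n_atoms(variant)), pairs[, 2])
  }
  if (!is.null(parent) && !is.null(variant)) {
    if (!all(parent$elements[pairs[, 1]] == variant$elements[pairs[, 2]]))
      stop("mapped atoms disagree in element", call. = FALSE)
  }
  .atom_map(pairs, ua, ub)
}
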