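#' Farthest atom pair of a molecule
#'
#' The baseline of the canonical ligand frame: the two atoms at maximal
#' Euclidean distance.  Ties are broken by the lexicographically
#' smallest index pair, and `i < j` always.
#'
#' @param mol a [molecule()].
#' @return list with integer `i`, `j` and `distance` (Angstrom).
#' @export
farthest_pair <- function(mol) {
  stopifnot(inherits(mol, "molecule"), n_atoms(mol) >= 2L)
  D <- as.matrix(stats::dist(mol$coords))
  D[lower.tri(D, diag = TRUE)] <- -Inf
  mx <- max(D)
  hits <- which(D >= mx - 1e-12, arr.ind = TRUE)
  # lexicographically smallest (i, j) among the ties
  ord <- order(hits[, 1], hits[, 2])
  i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
  list(i = as.integer(i), j = as.integer(j), distance = mx)
}

#' Canonical, similarity-invariant ligand orientation
#'
#' Centers the ligand at its centroid and rotates it so that the
#' coordinate variances decrease along x, y, z (the orthogonal
#' directions of maximal spatial variability).  Principal axes alone
#' leave a sign/reflection ambiguity, so signs are fixed
#' deterministically, in a way that keeps the transform a proper
#' rotation (det = +1, chirality preserved):
#' \itemize{
#'   \item x is oriented so the first baseline atom (the smaller index
#'     of the farthest pair) has non-positive x;
#'   \item y is oriented so the atom of maximal |y| has positive y
#'     (ties: smaller index);
#'   \item the z sign is forced by det = +1.
#' }
#' Physical scale is preserved (no size normalization): docking needs
#' real Angstrom dimensions.  When two coordinate variances tie within
#' `tie_tol` the principal directions are not unique; the frame then
#' falls back to the baseline direction as the x axis (with the same
#' sign rules) and a warning is emitted.
#'
#' @param mol a [molecule()], k >= 4.
#' @param tie_tol relative tolerance for declaring a variance tie.
#' @return list with `frame` (class `template_frame`: fields `rotation`
#'   3x3 proper rotation, `translation`, `baseline`, `axis_variances`)
#'   and `template` (the reoriented [molecule()]).  Canonical
#'   coordinates are `(coords + translation) %*% t(rotation)` applied
#'   row-wise, i.e. `rotation %*% (x - centroid)` per atom.
#' @export
canonical_template <- function(mol, tie_tol = 1e-9) {
  stopifnot(inherits(mol, "molecule"))
  k <- n_atoms(mol)
  if (k < 4L) stop("canonical frame needs k >= 4 atoms", call. = FALSE)
  bl <- farthest_pair(mol)
  centroid <- colMeans(mol$coords)
  C <- sweep(mol$coords, 2, centroid)
  S <- stats::cov(C)
  eg <- eigen(S, symmetric = TRUE)      # eigenvalues descending
  ev <- eg$values
  tied <- any(diff(ev) > -tie_tol * max(abs(ev), 1))
  if (tied) {
    warning("coordinate variances tie within tolerance; falling back ",
            "to the baseline direction as the x axis", call. = FALSE)
    u <- C[bl$j, ] - C[bl$i, ]
    u <- u / sqrt(sum(u^2))
    # maximal-variance direction orthogonal to the baseline
    P <- diag(3) - tcrossprod(u)
    eg2 <- eigen(P %*% S %*% P, symmetric = TRUE)
    v <- eg2$vectors[, 1]
    v <- v - sum(v * u) * u
    v <- v / sqrt(sum(v^2))
    E <- cbind(u, v, c(u[2] * v[3] - u[3] * v[2],
                       u[3] * v[1] - u[1] * v[3],
                       u[1] * v[2] - u[2] * v[1]))
  } else {
    E <- eg$vectors
  }
  Y <- C %*% E
  if (Y[bl$i, 1] > 0) { E[, 1] <- -E[, 1]; Y[, 1] <- -Y[, 1] }
  jmax <- which.max(abs(Y[, 2]))
  if (Y[jmax, 2] < 0) { E[, 2] <- -E[, 2]; Y[, 2] <- -Y[, 2] }
  if (det(E) < 0) { E[, 3] <- -E[, 3]; Y[, 3] <- -Y[, 3] }
  R <- t(E)                              # x_new = R %*% (x - centroid)
  v_axes <- apply(Y, 2, stats::var)
  template <- mol
  template$coords <- Y
  dimnames(template$coords) <- list(NULL, c("x", "y", "z"))
  frame <- structure(list(rotation = R, translation = -centroid,
                          baseline = c(bl$i, bl$j),
                          axis_variances = v_axes),
                     class = "template_frame")
  list(frame = frame, template = template)
}

#' @export
print.template_frame <- function(x, ...) {
  cat(sprintf(paste0("<template_frame> baseline atoms (%d, %d); axis ",
                     "variances %.3f >= %.3f >= %.3f A^2\n"),
              x$baseline[1], x$baseline[2], x$axis_variances[1],
              x$axis_variances[2], x$axis_variances[3]))
  invisible(x)
}

# Exact 90-degree-multiple rotation about axis 1 (x), 2 (y) or 3 (z);
# sin/cos of the multiples are taken as exact 0/±1.
.exact_rotation <- function(axis, deg) {
  q <- (deg %/% 90L) %% 4L
  cs <- c(1, 0, -1, 0)[q + 1L]
  sn <- c(0, 1, 0, -1)[q + 1L]
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- cs; R[ax[2], ax[2]] <- cs
  R[ax[1], ax[2]] <- -sn; R[ax[2], ax[1]] <- sn
  R
}

#' Ten-member rotation ensemble of a canonical template
#'
#' The template plus nine rigid copies rotated by 90, 180 and 270
#' degrees in the xy, xz and yz planes (i.e. about the z, y and x axes
#' respectively), about the template centroid.  Rotations are exact:
#' the sines and cosines of the quarter turns are 0/±1, so re-applying
#' a 90-degree turn four times reproduces the template bit-for-bit.
#'
#' @param template the [molecule()] returned by [canonical_template()].
#' @return object of class `rotation_ensemble`: named list `members`
#'   with tags `none`, `xy90`, `xy180`, `xy270`, `xz90`, `xz180`,
#'   `xz270`, `yz90`, `yz180`, `yz270`.
#' @export
rotation_ensemble <- function(template) {
  stopifnot(inherits(template, "molecule"))
  plane_axis <- c(xy = 3L, xz = 2L, yz = 1L)
  centroid <- colMeans(template$coords)
  C <- sweep(template$coords, 2, centroid)
  members <- list(none = template)
  for (plane in names(plane_axis)) {
    for (deg in c(90L, 180L, 270L)) {
      R <- .exact_rotation(plane_axis[[plane]], deg)
      m <- template
      m$coords <- sweep(C %*% t(R), 2, centroid, "+")
      dimnames(m$coords) <- list(NULL, c("x", "y", "z"))
      m$name <- paste0(template$name, "_", plane, deg)
      members[[paste0(plane, deg)]] <- m
    }
  }
  structure(list(members = members, tags = names(members)),
            class = "rotation_ensemble")
}

#' @export
print.rotation_ensemble <- function(x, ...) {
  cat(sprintf("<rotation_ensemble> %d members: %s\n", length(x$members),
              paste(x$tags, collapse = ", ")))
  invisible(x)
}

#' Docking grid box
#'
#' Defaults reproduce the xanthine-oxidase active-site box used
#' throughout this package: 20 x 20 x 20 Angstrom centered at
#' (26, 10, 118).
#'
#' @param center length-3 numeric, Angstrom.
#' @param size length-3 positive numeric, Angstrom.
#' @return list of class `grid_box`.
#' @export
grid_box <- function(center = c(26, 10, 118), size = c(20, 20, 20)) {
  stopifnot(length(center) == 3L, length(size) == 3L, all(size > 0))
  structure(list(center = as.numeric(center), size = as.numeric(size)),
            class = "grid_box")
}

#' Emit ligand files and docking configurations for an ensemble
#'
#' Writes one ligand coordinate file and one Vina-style configuration
#' file per ensemble member, plus a tab-separated manifest.  The
#' configuration carries `receptor`, `ligand`, `center_x/y/z` and
#' `size_x/y/z` (defaults: the [grid_box()] defaults) and an optional
#' `exhaustiveness` passthrough.  Docking itself is external.
#'
#' @param ensemble a [rotation_ensemble()].
#' @param box a [grid_box()].
#' @param receptor path to the (already prepared) receptor file.
#' @param outdir output directory, created if needed.
#' @param format ligand file format (`"pdbqt"` needs PDBQT provenance on
#'   the template; see [write_structure()]).
#' @param exhaustiveness optional integer passthrough.
#' @return invisibly, the manifest data.frame (`tag`, `ligand`,
#'   `config`).
#' @export
emit_docking_job <- function(ensemble, box = grid_box(), receptor,
                             outdir, format = "pdb",
                             exhaustiveness = NULL) {
  stopifnot(inherits(ensemble, "rotation_ensemble"),
            inherits(box, "grid_box"))
  if (!file.exists(receptor))
    stop("receptor file not found: ", receptor, call. = FALSE)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  rows <- lapply(ensemble$tags, function(tag) {
    lig <- file.path(outdir, paste0("ligand_", tag, ".", format))
    write_structure(ensemble$members[[tag]], lig, format = format)
    cfg <- file.path(outdir, paste0("config_", tag, ".txt"))
    lines <- c(paste0("receptor = ", receptor),
               paste0("ligand = ", lig),
               sprintf("center_x = %s", format(box$center[1])),
               sprintf("center_y = %s", format(box$center[2])),
               sprintf("center_z = %s", format(box$center[3])),
               sprintf("size_x = %s", format(box$size[1])),
               sprintf("size_y = %s", format(box$size[2])),
               sprintf("size_z = %s", format(box$size[3])))
    if (!is.null(exhaustiveness))
      lines <- c(lines, paste0("exhaustiveness = ", exhaustiveness))
    writeLines(lines, cfg)
    data.frame(tag = tag, ligand = lig, config = cfg,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Collate docking scores from Vina result files
#'
#' Accepts Vina stdout logs (the `mode | affinity` table) and/or docked
#' PDBQT files (`REMARK VINA RESULT:` records).  The best (lowest)
#' affinity per file is reported; the member tag is taken from the
#' names of `paths` when present, otherwise from the file name.
#'
#' @param paths character vector of result files, optionally named by
#'   ensemble tag.
#' @return data.frame (`tag`, `best_affinity` in kcal/mol) with an
#'   attribute `summary` = list(min, max, spread).  Unparseable files
#'   are dropped with a warning.
#' @export
collate_scores <- function(paths) {
  tags <- names(paths) %||% rep(NA_character_, length(paths))
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    tag <- if (!is.na(tags[i]) && nzchar(tags[i])) tags[i] else
      tools::file_path_sans_ext(basename(p))
    aff <- tryCatch(.parse_vina(p), error = function(e) {
      warning("cannot parse '", p, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(aff)) next
    rows[[length(rows) + 1L]] <-
      data.frame(tag = tag, best_affinity = min(aff),
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no parseable result files", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(min = min(out$best_affinity),
                               max = max(out$best_affinity),
                               spread = diff(range(out$best_affinity)))
  out
}

.parse_vina <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rem <- grep("^REMARK VINA RESULT:", lines, value = TRUE)
  if (length(rem)) {
    aff <- suppressWarnings(as.numeric(vapply(strsplit(trimws(
      sub("^REMARK VINA RESULT:", "", rem)), "\\s+"), `[`, "", 1L)))
    aff <- aff[!is.na(aff)]
    if (length(aff)) return(aff)
  }
  # stdout log table: "   1   -7.5   0.000   0.000"
  tab <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s", lines, value = TRUE)
  aff <- suppressWarnings(as.numeric(vapply(strsplit(trimws(tab),
                                                     "\\s+"), `[`, "",
                                            2L)))
  aff <- aff[!is.na(aff)]
  if (!length(aff)) stop("no affinity records found")
  aff
}
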