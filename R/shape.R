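#' Preshape of a configuration
#'
#' Removes translation (centering at the centroid) and scale (division
#' by centroid size, the Frobenius norm of the centered coordinates).
#' The result is a point on the preshape hypersphere; rotation is
#' removed later, at distance time, by Procrustes alignment.
#'
#' @param mol a [molecule()].
#' @param subset optional integer vector of atom indices.
#' @return object of class `preshape`: list with `Z` (k x 3, centered,
#'   unit Frobenius norm), `centroid` (3-vector, Angstrom), `size`
#'   (centroid size, Angstrom) and `k`.  A logical attribute
#'   `collinear` flags rank-deficient (collinear) configurations, which
#'   are permitted but noted.
#' @export
preshape <- function(mol, subset = NULL) {
  X <- if (inherits(mol, "molecule")) mol$coords else as.matrix(mol)
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  k <- nrow(X)
  if (k < 3L)
    stop("preshape needs at least 3 atoms (got ", k, ")", call. = FALSE)
  centroid <- colMeans(X)
  C <- sweep(X, 2, centroid)
  size <- sqrt(sum(C^2))
  if (size < 1e-12)
    stop("degenerate configuration: all atoms coincident", call. = FALSE)
  Z <- C / size
  sv <- svd(Z, nu = 0, nv = 0)$d
  out <- structure(list(Z = Z, centroid = centroid, size = size, k = k),
                   class = "preshape")
  attr(out, "collinear") <- sv[2] < 1e-9
  out
}

#' @export
print.preshape <- function(x, ...) {
  cat(sprintf("<preshape> k = %d, centroid size = %.4f A%s\n", x$k,
              x$size,
              if (isTRUE(attr(x, "collinear"))) " [collinear]" else ""))
  invisible(x)
}

# Partial-Procrustes inner product between two coordinate sets.
# Returns the aligned inner product (cos of the shape distance), the
# optimal rotation R (acting on B: B_aligned = Z_B %*% t(R)) and the rd.
.rd_svd <- function(XA, XB, mode) {
  pa <- preshape(XA); pb <- preshape(XB)
  M <- crossprod(pa$Z, pb$Z)            # 3 x 3
  sv <- svd(M)
  lam <- sv$d                           # descending
  if (mode == "proper_rotation") {
    s <- sign(det(sv$u %*% t(sv$v)))
    if (s == 0) s <- 1
    inner <- lam[1] + lam[2] + s * lam[3]
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  } else {
    inner <- sum(lam)
    R <- sv$u %*% t(sv$v)
  }
  inner <- .clip1(inner)
  list(rd = .chord_angle(pa$Z, pb$Z, R), inner = inner, R = R,
       collinear = isTRUE(attr(pa, "collinear")) ||
                   isTRUE(attr(pb, "collinear")))
}

# Angle between unit preshapes from the aligned chord length:
# ||za - zb R^T||^2 = 2 - 2 cos(theta), so theta = 2 asin(chord / 2).
# Equivalent to acos of the inner product but numerically stable near 0
# (acos loses half the significant digits at cos ~ 1).
.chord_angle <- function(za, zb, R) {
  chord <- sqrt(sum((za - zb %*% t(R))^2))
  2 * asin(min(1, chord / 2))
}

.clip1 <- function(x) {
  if (abs(x) > 1 + 1e-12)
    warning("alignment inner product ", format(x),
            " outside [-1, 1] beyond numerical tolerance")
  min(1, max(-1, x))
}

#' Riemannian shape distance between two molecules
#'
#' The Riemannian distance (RD) is the angle between the two preshapes
#' after optimal rotation alignment: with preshapes \eqn{Z_A, Z_B} and
#' the SVD \eqn{Z_A^T Z_B = U \Lambda V^T} (singular values
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0}),
#' \deqn{RD = \arccos(\lambda_1 + \lambda_2 \pm \lambda_3),}
#' where in `proper_rotation` mode the smallest singular value is
#' negated when \eqn{\det(UV^T) < 0} (no reflection may enter, so
#' chirality is discriminated), and in `allow_reflection` mode the plain
#' sum is used.  RD ranges from 0 (identical shapes) to \eqn{\pi/2}.
#'
#' Per-element subspace distances are reported for every element with at
#' least three matched atoms.  With `refit = TRUE` (default) each
#' subspace gets its own Procrustes fit; with `refit = FALSE` the
#' global optimal rotation is inherited and the subspace angle is the
#' arccosine of the subspace preshape inner product under that rotation.
#'
#' @param A,B [molecule()] objects.
#' @param map an `atom_map` from [match_atoms()] or [read_atom_map()];
#'   computed automatically when `NULL`.
#' @param mode `"proper_rotation"` (default; chirality-preserving) or
#'   `"allow_reflection"`.
#' @param subset optional restriction before any computation: a
#'   character vector of element symbols or an integer vector of atom
#'   indices in `A`.
#' @param refit logical; see above.
#' @return object of class `shape_distance`: `rd` (radians), `mode`,
#'   `n_atoms` (matched count used), `by_element` (named numeric),
#'   `refit`, plus the optimal `rotation` and the aligned `inner`
#'   product.
#' @examples
#' a <- random_molecule(8, seed = 1)
#' b <- transform_molecule(a, rotation = diag(3), translation = c(1, 2, 3))
#' riemannian_distance(a, b)$rd   # 0: shape is translation-invariant
#' @export
riemannian_distance <- function(A, B, map = NULL,
                                mode = c("proper_rotation",
                                         "allow_reflection"),
                                subset = NULL, refit = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "molecule"), inherits(B, "molecule"))
  if (is.null(map)) map <- match_atoms(A, B)
  pairs <- map$pairs
  if (!is.null(subset)) {
    keep <- if (is.character(subset)) {
      A$elements[pairs[, 1]] %in% subset
    } else {
      pairs[, 1] %in% as.integer(subset)
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) < 3L)
    stop("fewer than 3 matched atoms after subsetting", call. = FALSE)
  XA <- A$coords[pairs[, 1], , drop = FALSE]
  XB <- B$coords[pairs[, 2], , drop = FALSE]
  g <- .rd_svd(XA, XB, mode)
  els <- A$elements[pairs[, 1]]
  by_el <- numeric(0)
  for (el in unique(els)) {
    sel <- which(els == el)
    if (length(sel) < 3L) {
      warning("element subspace '", el, "' has fewer than 3 matched ",
              "atoms; skipped", call. = FALSE)
      next
    }
    by_el[[el]] <- if (refit) {
      .rd_svd(XA[sel, , drop = FALSE], XB[sel, , drop = FALSE], mode)$rd
    } else {
      za <- preshape(XA[sel, , drop = FALSE])$Z
      zb <- preshape(XB[sel, , drop = FALSE])$Z
      .chord_angle(za, zb, g$R)
    }
  }
  structure(list(rd = g$rd, mode = mode, n_atoms = nrow(pairs),
                 by_element = by_el, refit = refit, rotation = g$R,
                 inner = g$inner),
            class = "shape_distance")
}

#' @export
print.shape_distance <- function(x, ...) {
  cat(sprintf("<shape_distance> rd = %.3f rad (%s, %d atoms%s)\n",
              x$rd, x$mode, x$n_atoms,
              if (x$refit) ", refit subspaces" else ", inherited rotation"))
  if (length(x$by_element))
    cat("  by element:",
        paste(sprintf("%s = %.3f", names(x$by_element), x$by_element),
              collapse = ", "), "\n")
  invisible(x)
}

#' Brute-force shape-distance oracle
#'
#' Independent check on [riemannian_distance()]: maximizes the preshape
#' inner product over rotations parameterized by unit quaternions with a
#' dense multi-start quasi-Newton search (no SVD involved).  In
#' `allow_reflection` mode the search is repeated against the reflected
#' configuration and the larger inner product wins.  Intended for small
#' instances (k <= 12) in tests.
#'
#' @inheritParams riemannian_distance
#' @param n_starts number of random quaternion starts (plus identity).
#' @return the distance in radians.
#' @export
rd_oracle <- function(A, B, map = NULL,
                      mode = c("proper_rotation", "allow_reflection"),
                      n_starts = 16L) {
  mode <- match.arg(mode)
  if (is.null(map)) map <- match_atoms(A, B)
  XA <- A$coords[map$pairs[, 1], , drop = FALSE]
  XB <- B$coords[map$pairs[, 2], , drop = FALSE]
  za <- preshape(XA)$Z
  zb <- preshape(XB)$Z
  best <- .quat_maximize(za, zb, n_starts)
  if (mode == "allow_reflection") {
    zbr <- zb %*% diag(c(1, 1, -1))
    best <- max(best, .quat_maximize(za, zbr, n_starts))
  }
  acos(.clip1(best))
}

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.quat_maximize <- function(za, zb, n_starts) {
  f <- function(q) {
    if (sum(q^2) < 1e-12) return(1e6)
    -sum(za * (zb %*% t(.quat_to_rot(q))))
  }
  starts <- with_seed(20220321L, {
    rbind(c(1, 0, 0, 0),
          matrix(stats::rnorm(4L * n_starts), ncol = 4L))
  })
  best <- -Inf
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], f, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500L))
    best <- max(best, -opt$value)
  }
  best
}

#' Shape-distance table for a family of variants
#'
#' One row per variant (typically the site-specific anions of one
#' parent compound): label, global RD, per-element subspace RDs and the
#' matched atom count.  Full precision is retained; the print method
#' rounds to three decimals for display.
#'
#' @param parent a [molecule()].
#' @param variants a named list of molecules, or a list of lists with
#'   fields `label`, `mol` and optionally `map`.
#' @inheritParams riemannian_distance
#' @return a `data.frame` of class `rd_table` with columns `label`,
#'   `rd`, one `rd_<element>` column per element seen, and `n_atoms`.
#' @export
rd_table <- function(parent, variants,
                     mode = c("proper_rotation", "allow_reflection"),
                     refit = TRUE) {
  mode <- match.arg(mode)
  norm <- lapply(seq_along(variants), function(i) {
    v <- variants[[i]]
    if (inherits(v, "molecule"))
      list(label = names(variants)[i] %||% v$name, mol = v, map = NULL)
    else
      list(label = v$label, mol = v$mol, map = v$map %||% NULL)
  })
  res <- lapply(norm, function(v)
    riemannian_distance(parent, v$mol, map = v$map, mode = mode,
                        refit = refit))
  els <- unique(unlist(lapply(res, function(r) names(r$by_element))))
  tab <- data.frame(label = vapply(norm, `[[`, "", "label"),
                    rd = vapply(res, `[[`, 0, "rd"),
                    stringsAsFactors = FALSE)
  for (el in els)
    tab[[paste0("rd_", el)]] <- vapply(res, function(r)
      r$by_element[el][[1]] %||% NA_real_, 0)
  tab$n_atoms <- vapply(res, `[[`, 0L, "n_atoms")
  structure(tab, class = c("rd_table", "data.frame"),
            mode = mode, refit = refit)
}

#' @export
print.rd_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE) & names(y) != "n_atoms"
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a shape-distance table
#'
#' Tab-separated values at full precision, or JSON via `format = "json"`.
#'
#' @param tab an [rd_table()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_rd_table <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(tab), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(tab), path, dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
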