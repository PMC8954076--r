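#' Reference enthalpies of the proton, electron and hydrogen atom
#'
#' Defaults are the standard aqueous-phase values used with
#' IEFPCM-solvated DFT enthalpies: H(H+) = -259.00, H(e-) = -55.61 and
#' H(H.) = -314.65 kcal/mol at 298.15 K.
#'
#' @param H_proton,H_electron,H_hydrogen_atom kcal/mol.
#' @return list of class `reference_enthalpies`.
#' @export
reference_enthalpies <- function(H_proton = -259.00, H_electron = -55.61,
                                 H_hydrogen_atom = -314.65) {
  stopifnot(is.finite(H_proton), is.finite(H_electron),
            is.finite(H_hydrogen_atom))
  structure(list(H_proton = H_proton, H_electron = H_electron,
                 H_hydrogen_atom = H_hydrogen_atom),
            class = "reference_enthalpies")
}

# delta = H(H.) - H(H+) - H(e-): the exact offset linking the two
# thermodynamic cycles, BDE = PA + ETE + delta = IP + PDE + delta.
cycle_delta <- function(ref = reference_enthalpies()) {
  ref$H_hydrogen_atom - ref$H_proton - ref$H_electron
}

#' Convert hartree to kcal/mol (and back)
#'
#' Fixed factor 627.5095 kcal/mol per hartree.
#' @param x numeric.
#' @return numeric.
#' @export
hartree_to_kcal <- function(x) x * .HARTREE_KCAL

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / .HARTREE_KCAL

.ROLES <- c("parent", "radical", "anion", "cation_radical")

#' Read a species-enthalpy table
#'
#' Delimiter-separated values (TSV/CSV, autodetected) or JSON with
#' columns/fields `compound`, `site`, `role`, `H` and optionally `unit`
#' (`"hartree"` or `"kcal/mol"`).  Roles: `parent` (ArOH), `radical`
#' (ArO.), `anion` (ArO-), `cation_radical` (ArOH+.).
#'
#' @param path file path.
#' @return data.frame of species enthalpies.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  }
  need <- c("compound", "site", "role", "H")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("species table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$role), .ROLES)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df
}

.to_kcal <- function(H, unit) {
  unit <- tolower(unit)
  ok <- unit %in% c("hartree", "kcal/mol", "kcal")
  if (!all(ok))
    stop("unknown enthalpy unit(s): ",
         paste(unique(unit[!ok]), collapse = ", "), call. = FALSE)
  ifelse(unit == "hartree", hartree_to_kcal(H), H)
}

#' Compute the five antioxidant descriptors from species enthalpies
#'
#' For each deprotonation/abstraction site of one compound:
#' \deqn{BDE = H(ArO.) + H(H.) - H(ArOH)}
#' \deqn{PA  = H(ArO-) + H(H+) - H(ArOH)}
#' \deqn{ETE = H(ArO.) + H(e-) - H(ArO-)}
#' \deqn{IP  = H(ArOH+.) + H(e-) - H(ArOH)}
#' \deqn{PDE = H(ArO.) + H(H+) - H(ArOH+.)}
#' all in kcal/mol (hartree inputs are converted at 627.5095).  BDE
#' drives the one-step hydrogen-atom transfer (HAT), PA + ETE the
#' proton-loss-then-electron-transfer sequence (SPLET) and IP + PDE the
#' electron-transfer-then-deprotonation sequence (SET-PT).  IP is a
#' property of the compound, so it is constant down the table.
#'
#' @param species data.frame with columns `compound`, `site`, `role`,
#'   `H` and optionally `unit` (see [read_species_table()]); exactly one
#'   compound, one `parent` row and at most one `cation_radical` row.
#' @param ref a [reference_enthalpies()].
#' @param unit default unit when the table has no `unit` column
#'   (`"kcal/mol"` or `"hartree"`).
#' @return a `descriptor_table`: data.frame with columns `site`, `BDE`,
#'   `PA`, `ETE`, `IP`, `PDE` (kcal/mol; `NA` with a warning where the
#'   required species is absent), attribute `compound` and `reference`.
#' @seealso [cycle_residuals()], [rank_sites()], [classify_mechanism()]
#' @export
compute_descriptors <- function(species, ref = reference_enthalpies(),
                                unit = "kcal/mol") {
  species <- as.data.frame(species)
  if (length(unique(species$compound)) != 1L)
    stop("`species` must describe exactly one compound; got: ",
         paste(unique(species$compound), collapse = ", "),
         "\n(use lapply(split(species, species$compound), ",
         "compute_descriptors) for several)", call. = FALSE)
  if (is.null(species$unit)) species$unit <- unit
  H <- .to_kcal(species$H, species$unit)
  role <- species$role
  if (sum(role == "parent") != 1L)
    stop("exactly one parent species required", call. = FALSE)
  if (sum(role == "cation_radical") > 1L)
    stop("at most one cation_radical species allowed", call. = FALSE)
  H_par <- H[role == "parent"]
  H_cat <- if (any(role == "cation_radical"))
    H[role == "cation_radical"] else NA_real_
  sites <- unique(species$site[role %in% c("radical", "anion")])
  pick <- function(s, r) {
    i <- which(species$site == s & role == r)
    if (length(i)) H[i[1L]] else NA_real_
  }
  rows <- lapply(sites, function(s) {
    H_rad <- pick(s, "radical"); H_an <- pick(s, "anion")
    data.frame(
      site = s,
      BDE = H_rad + ref$H_hydrogen_atom - H_par,
      PA  = H_an + ref$H_proton - H_par,
      ETE = H_rad + ref$H_electron - H_an,
      IP  = H_cat + ref$H_electron - H_par,
      PDE = H_rad + ref$H_proton - H_cat,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  nmiss <- sum(is.na(as.matrix(tab[-1])))
  if (nmiss)
    warning(nmiss, " descriptor cell(s) missing (absent species)",
            call. = FALSE)
  as_descriptor_table(tab, compound = unique(species$compound),
                      reference = ref)
}

#' Build a descriptor table from already-computed values
#'
#' Used for externally supplied tables, e.g. published descriptor values
#' rounded to one decimal.
#'
#' @param df data.frame with column `site` and any of `BDE`, `PA`,
#'   `ETE`, `IP`, `PDE` (kcal/mol).
#' @param compound compound name.
#' @param reference a [reference_enthalpies()].
#' @return a `descriptor_table`.
#' @export
as_descriptor_table <- function(df, compound = "compound",
                                reference = reference_enthalpies()) {
  df <- as.data.frame(df)
  stopifnot("site" %in% names(df))
  for (col in c("BDE", "PA", "ETE", "IP", "PDE"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df <- df[c("site", "BDE", "PA", "ETE", "IP", "PDE")]
  structure(df, class = c("descriptor_table", "data.frame"),
            compound = compound, reference = reference)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table for %s (kcal/mol)\n",
              attr(x, "compound")))
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Thermodynamic-cycle residuals of a descriptor table
#'
#' Both two-step mechanisms must close onto the one-step cycle:
#' BDE - PA - ETE and BDE - IP - PDE each equal
#' \eqn{\delta = H(H.) - H(H+) - H(e-)} exactly.  For internally
#' computed tables the residuals are zero to machine precision; for
#' externally supplied tables rounded to one decimal they are bounded by
#' `tol` (default 0.15 kcal/mol, i.e. two half-unit roundings plus the
#' rounded \eqn{\delta}).  Rows breaking the tolerance are flagged, not
#' corrected: a flagged row in a published table usually indicates a
#' transcription problem.
#'
#' @param table a `descriptor_table`.
#' @param ref a [reference_enthalpies()].
#' @param tol flag threshold in kcal/mol.
#' @return data.frame with `site`, `splet_residual`, `setpt_residual`
#'   and logical `splet_ok` / `setpt_ok` (NA where cells are missing).
#' @export
cycle_residuals <- function(table, ref = attr(table, "reference") %||%
                              reference_enthalpies(), tol = 0.15) {
  stopifnot(inherits(table, "descriptor_table"))
  d <- cycle_delta(ref)
  rs <- table$BDE - table$PA - table$ETE - d
  rp <- table$BDE - table$IP - table$PDE - d
  data.frame(site = table$site,
             splet_residual = rs, setpt_residual = rp,
             splet_ok = abs(rs) <= tol, setpt_ok = abs(rp) <= tol,
             stringsAsFactors = FALSE)
}

#' Rank deprotonation sites by a descriptor
#'
#' Ascending order (the thermodynamically easiest site first).  Ties are
#' broken by input order and reported via the `ties` attribute.
#'
#' @param table a `descriptor_table`.
#' @param by one of `"PA"` (default), `"BDE"`, `"ETE"`, `"PDE"`.
#' @return character vector of site labels, attribute `values` with the
#'   sorted values and `ties` (logical).
#' @export
rank_sites <- function(table, by = "PA") {
  stopifnot(inherits(table, "descriptor_table"))
  by <- match.arg(by, c("PA", "BDE", "ETE", "PDE"))
  v <- table[[by]]
  keep <- !is.na(v)
  if (!any(keep)) stop("descriptor ", by, " absent", call. = FALSE)
  ord <- order(v[keep])          # stable: ties keep input order
  out <- table$site[keep][ord]
  attr(out, "values") <- v[keep][ord]
  attr(out, "ties") <- anyDuplicated(v[keep]) > 0L
  out
}

#' Classify the thermodynamically favored radical-scavenging mechanism
#'
#' Compares the first-step descriptors: min-over-sites BDE (HAT),
#' min-over-sites PA (SPLET) and IP (SET-PT); the mechanism with the
#' smallest first step wins.  On ties the polar-medium preference order
#' SPLET > HAT > SET-PT applies and the tie is reported.
#'
#' @param table a `descriptor_table`.
#' @return list with `mechanism` (`"HAT"`, `"SPLET"` or `"SET-PT"`),
#'   `values` (named triple of the compared minima), `site` (the argmin
#'   site of the winning descriptor, `NA` for SET-PT) and `tie`.
#' @export
classify_mechanism <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  cand <- c(SPLET = suppressWarnings(min(table$PA, na.rm = TRUE)),
            HAT = suppressWarnings(min(table$BDE, na.rm = TRUE)),
            `SET-PT` = suppressWarnings(min(table$IP, na.rm = TRUE)))
  cand[!is.finite(cand)] <- NA_real_
  if (all(is.na(cand)))
    stop("need at least one of BDE, PA, IP", call. = FALSE)
  best <- names(cand)[which.min(cand)]   # ties: order SPLET, HAT, SET-PT
  tie <- sum(cand == min(cand, na.rm = TRUE), na.rm = TRUE) > 1L
  site <- switch(best,
                 SPLET = table$site[which.min(table$PA)],
                 HAT = table$site[which.min(table$BDE)],
                 `SET-PT` = NA_character_)
  list(mechanism = best,
       values = c(HAT = cand[["HAT"]], SPLET = cand[["SPLET"]],
                  `SET-PT` = cand[["SET-PT"]]),
       site = site, tie = tie)
}

#' Concordance between proton affinity and shape distance
#'
#' Tests whether the global Riemannian distance of each anion to its
#' parent preserves the ranking given by the proton affinity: a Kendall
#' rank correlation over the shared sites, with the discordant site
#' pairs listed.
#'
#' @param desc a `descriptor_table` with a `PA` column.
#' @param rds an [rd_table()] (or data.frame with `label`/`site` and
#'   `rd`).  Labels are matched against the descriptor sites; a label
#'   such as `"IsoBdAC17"` matches site `"C17"` by suffix.
#' @return list with `concordance` (Kendall tau in \[-1, 1\]),
#'   `n_sites`, `pairs` (data.frame of compared site pairs with a
#'   `concordant` flag) and `discordant` (labels of discordant pairs).
#' @export
rd_pa_concordance <- function(desc, rds) {
  stopifnot(inherits(desc, "descriptor_table"))
  rds <- as.data.frame(rds)
  key <- rds$site %||% rds$label
  site_of <- vapply(key, function(lbl) {
    hit <- desc$site[vapply(desc$site, function(s)
      endsWith(lbl, s) || lbl == s, TRUE)]
    if (length(hit)) hit[which.max(nchar(hit))] else NA_character_
  }, "")
  ok <- !is.na(site_of)
  m <- merge(data.frame(site = site_of[ok], rd = rds$rd[ok]),
             data.frame(site = desc$site, PA = desc$PA), by = "site")
  m <- m[!is.na(m$PA) & !is.na(m$rd), ]
  if (nrow(m) < 2L)
    stop("fewer than 2 shared sites between the tables", call. = FALSE)
  tau <- stats::cor(m$PA, m$rd, method = "kendall")
  cmb <- utils::combn(nrow(m), 2L)
  conc <- apply(cmb, 2L, function(ij) {
    s <- sign(m$PA[ij[1]] - m$PA[ij[2]]) * sign(m$rd[ij[1]] - m$rd[ij[2]])
    s >= 0
  })
  pairs <- data.frame(site_1 = m$site[cmb[1, ]], site_2 = m$site[cmb[2, ]],
                      concordant = conc, stringsAsFactors = FALSE)
  list(concordance = tau, n_sites = nrow(m), pairs = pairs,
       discordant = pairs[!pairs$concordant, c("site_1", "site_2")])
}

#' Published descriptor and shape-distance tables for the betalains
#'
#' `betalain_descriptors()` returns the published B3LYP/6-31+G(d,p)
#' aqueous-phase descriptor values (kcal/mol) for betanin (Bn),
#' isobetanin (IsoBn), betanidin (Bd) and isobetanidin (IsoBd) at their
#' deprotonation sites; `betalain_rd()` the published proton affinities
#' and parent-to-anion Riemannian distances (global and O/C/H
#' subspaces).  Shipped as plain-text tables under `extdata`.
#'
#' @param compound optional compound filter (`"Bn"`, `"IsoBn"`, `"Bd"`,
#'   `"IsoBd"`).
#' @return a data.frame.
#' @export
betalain_descriptors <- function(compound = NULL) {
  path <- system.file("extdata", "betalain_descriptors.tsv",
                      package = "betashape", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(compound)) df <- df[df$compound %in% compound, ]
  df
}

#' @rdname betalain_descriptors
#' @export
betalain_rd <- function(compound = NULL) {
  path <- system.file("extdata", "betalain_rd.tsv",
                      package = "betashape", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(compound)) df <- df[df$compound %in% compound, ]
  df
}
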