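#' Coarse-grained chain conformations
#'
#' A `ChainConformation` is a Ca trace plus virtual Cb positions, one per
#' residue. The chain is valid when consecutive Ca-Ca distances fall in
#' [3.6, 4.0] A and no non-bonded Ca pair comes closer than 3.4 A.
#'
#' @name conformation
NULL

BOND_MIN <- 3.6
BOND_MAX <- 4.0
BOND_IDEAL <- 3.8
CLASH_DIST <- 3.4

#' Construct a chain conformation
#'
#' @param ca n x 3 matrix of Ca coordinates (A).
#' @param sequence amino-acid string of length n; defaults to poly-alanine.
#' @param cb optional n x 3 matrix of Cb coordinates; rebuilt from the Ca
#'   trace with [virtual_cbeta()] when missing.
#' @return a `ChainConformation` with elements `n_res`, `ca`, `cb`,
#'   `sequence`.
#' @export
chain_conformation <- function(ca, sequence = NULL, cb = NULL) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3, nrow(ca) >= 2)
  n <- nrow(ca)
  sequence <- sequence %||% strrep("A", n)
  if (nchar(sequence) != n) {
    cf_abort("cf_length_mismatch_error",
             "sequence length %d != %d residues", nchar(sequence), n)
  }
  if (is.null(cb)) cb <- virtual_cbeta(ca)
  structure(list(n_res = n, ca = unname(ca), cb = unname(as.matrix(cb)),
                 sequence = sequence),
            class = "ChainConformation")
}

#' @export
print.ChainConformation <- function(x, ...) {
  cat(sprintf("ChainConformation: %d residues\n", x$n_res))
  invisible(x)
}

#' Virtual Cb positions from a Ca trace
#'
#' For each interior residue the Cb is placed 1.53 A from the Ca along a
#' fixed combination of the bisector of the two flanking pseudo-bonds and
#' the local chain normal (ideal-geometry construction). Terminal residues
#' and collinear stretches fall back to a perpendicular offset; this keeps
#' the construction total and rotation-equivariant.
#'
#' @param ca n x 3 matrix of Ca coordinates.
#' @return n x 3 matrix of Cb coordinates.
#' @export
virtual_cbeta <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  cb <- ca
  if (n < 3) {
    off <- perp_unit(ca[min(2, n), ] - ca[1, ])
    return(ca + matrix(rep(1.53 * off, n), ncol = 3, byrow = TRUE))
  }
  prev <- ca[1:(n - 2), , drop = FALSE]
  here <- ca[2:(n - 1), , drop = FALSE]
  nxt <- ca[3:n, , drop = FALSE]
  u1 <- prev - here
  u2 <- nxt - here
  rn <- function(m) {
    l <- sqrt(rowSums(m * m))
    m / pmax(l, 1e-12)
  }
  u1 <- rn(u1); u2 <- rn(u2)
  bis <- u1 + u2
  nrm <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
               u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
               u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  bl <- sqrt(rowSums(bis * bis))
  nl <- sqrt(rowSums(nrm * nrm))
  ok <- bl > 1e-8 & nl > 1e-8
  dir <- matrix(0, n - 2, 3)
  # 1.53 A offset split between anti-bisector (in-plane) and normal
  dir[ok, ] <- -0.9 * bis[ok, , drop = FALSE] / bl[ok] +
    1.2373 * nrm[ok, , drop = FALSE] / nl[ok]
  if (any(!ok)) {
    for (k in which(!ok)) dir[k, ] <- 1.53 * perp_unit(u2[k, ])
  }
  cb[2:(n - 1), ] <- here + dir
  # termini: reuse the offset direction of the nearest interior residue
  cb[1, ] <- ca[1, ] + (cb[2, ] - ca[2, ])
  cb[n, ] <- ca[n, ] + (cb[n - 1, ] - ca[n - 1, ])
  cb
}

#' Check chain-geometry invariants
#'
#' @param conf a `ChainConformation`.
#' @param bond_range allowed consecutive Ca-Ca distance range.
#' @param clash_dist minimum non-bonded Ca-Ca distance.
#' @return `TRUE` if all invariants hold, else `FALSE`.
#' @export
validate_geometry <- function(conf, bond_range = c(BOND_MIN, BOND_MAX),
                              clash_dist = CLASH_DIST) {
  b <- bond_lengths(conf$ca)
  if (any(b < bond_range[1] - 1e-9 | b > bond_range[2] + 1e-9)) return(FALSE)
  !has_clash(conf$ca, clash_dist)
}

bond_lengths <- function(ca) {
  d <- diff(ca)
  sqrt(rowSums(d * d))
}

has_clash <- function(ca, clash_dist = CLASH_DIST) {
  n <- nrow(ca)
  if (n < 3) return(FALSE)
  dv <- as.vector(stats::dist(ca))
  i <- seq_len(n - 1)
  dv[(i - 1) * n - i * (i - 1) / 2 + 1] <- Inf  # bonded neighbours
  any(dv < clash_dist)
}

# --- minimal Ca-trace PDB IO (multi-model, CA/CB records only) -------------

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
AA1 <- stats::setNames(names(AA3), AA3)

format_atom <- function(serial, name, resname, resseq, xyz) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", name), resname, resseq,
          xyz[1], xyz[2], xyz[3])
}

conformation_pdb_lines <- function(conf, with_cb = TRUE) {
  aa <- strsplit(conf$sequence, "", fixed = TRUE)[[1]]
  res3 <- unname(AA3[aa])
  res3[is.na(res3)] <- "UNK"
  lines <- character(0)
  serial <- 1L
  for (r in seq_len(conf$n_res)) {
    lines <- c(lines, format_atom(serial, "CA", res3[r], r, conf$ca[r, ]))
    serial <- serial + 1L
    if (with_cb) {
      lines <- c(lines, format_atom(serial, "CB", res3[r], r, conf$cb[r, ]))
      serial <- serial + 1L
    }
  }
  lines
}

#' Write conformations as a (multi-model) PDB file
#'
#' Coarse-grained output: CA and virtual CB records only, chain A.
#'
#' @param confs a `ChainConformation` or list of them.
#' @param path output file path.
#' @param with_cb include virtual CB records (default TRUE).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(confs, path, with_cb = TRUE) {
  if (inherits(confs, "ChainConformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(conformation_pdb_lines(confs[[m]], with_cb), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read conformations from a (multi-model) Ca-trace PDB file
#'
#' Reads CA records (and CB when present) of chain models written by
#' [write_pdb()] or any PDB with per-residue CA atoms.
#'
#' @param path PDB file path.
#' @return list of `ChainConformation` objects, one per model.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) {
    cf_abort("cf_unreadable_error", "cannot read PDB file '%s'", path)
  }
  lines <- readLines(path, warn = FALSE)
  model_breaks <- grepl("^MODEL", lines)
  model_id <- cumsum(model_breaks)
  if (!any(model_breaks)) model_id <- rep(1L, length(lines))
  atom <- grepl("^ATOM", lines)
  out <- list()
  for (m in unique(model_id[atom])) {
    ml <- lines[atom & model_id == m]
    name <- trimws(substr(ml, 13, 16))
    res3 <- trimws(substr(ml, 18, 20))
    x <- as.numeric(substr(ml, 31, 38))
    y <- as.numeric(substr(ml, 39, 46))
    z <- as.numeric(substr(ml, 47, 54))
    is_ca <- name == "CA"
    if (!any(is_ca)) next
    ca <- cbind(x[is_ca], y[is_ca], z[is_ca])
    aa <- unname(AA1[res3[is_ca]])
    aa[is.na(aa)] <- "X"
    cb <- NULL
    if (sum(name == "CB") == sum(is_ca)) {
      cb <- cbind(x[name == "CB"], y[name == "CB"], z[name == "CB"])
    }
    out[[length(out) + 1L]] <-
      chain_conformation(ca, paste(aa, collapse = ""), cb = cb)
  }
  if (length(out) == 0L) {
    cf_abort("cf_parse_error", "no CA records found in '%s'", path)
  }
  out
}
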