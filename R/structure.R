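# Segment-wise structure comparison: common-atom pairing, Kabsch
# superposition on the 7TM backbone, and per-segment RMSD reporting.

TM_SEGMENTS <- paste0("TM", 1:7)
BACKBONE_ATOMS <- c("N", "CA", "C", "O")
RMSD_SCOPES <- c("7TM_all", "7TM_backbone", "ICL1", "ICL2", "ECL1", "ECL2",
                 "ECL3", "H8")

#' Construct a coordinate set
#'
#' Validates a tibble of heavy-atom coordinates for the RMSD machinery.
#'
#' @param df Tibble with columns `residue_number` (integer), `residue`
#'   (one-letter code), `atom` (PDB atom name), `x`, `y`, `z` (Angstrom),
#'   `segment` (topology segment label, e.g. `"TM5"`, `"ECL2"`), and
#'   optionally `generic` (generic position string) used as the pairing key
#'   when present.
#' @return The validated tibble with class `gpcr_coords`.
#' @export
coordinate_set <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("residue_number", "residue", "atom", "x", "y", "z", "segment")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("coordinate set lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("residue_number", "atom")])) {
    stop("duplicate (residue_number, atom) pairs in coordinate set",
         call. = FALSE)
  }
  class(df) <- unique(c("gpcr_coords", class(df)))
  df
}

#' Read coordinates from a PDB file
#'
#' Parses a standard PDB file with bio3d, keeping heavy (non-hydrogen) ATOM
#' records of one chain. For alternate locations the highest-occupancy
#' altloc is kept, making atom pairing deterministic. Segment assignment
#' (and optionally generic numbering) comes from a per-residue map such as
#' the output of [build_numbering_table()].
#'
#' @param path PDB file path.
#' @param segment_assignment Tibble mapping `residue_number` to `segment`
#'   (optionally also `struct_based` or `generic`); rows for unlisted
#'   residues get `NA` segments.
#' @param chain Chain identifier; default the first chain in the file.
#' @return A `gpcr_coords` tibble.
#' @export
read_coordinates <- function(path, segment_assignment, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  a <- tibble::as_tibble(pdb$atom)
  a <- a[a$type == "ATOM", ]
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, ]
  a <- a[is.na(a$elesy) | a$elesy != "H", ]
  a <- a[!grepl("^[0-9]*H", a$elety), ]
  # highest-occupancy altloc per (residue, atom)
  a <- dplyr::arrange(a, .data$resno, .data$elety,
                      dplyr::desc(tidyr::replace_na(.data$o, 1)))
  a <- dplyr::distinct(a, .data$resno, .data$elety, .keep_all = TRUE)
  out <- tibble::tibble(
    residue_number = a$resno,
    residue = aa_three_to_one(a$resid),
    atom = a$elety,
    x = a$x, y = a$y, z = a$z
  )
  sa <- tibble::as_tibble(segment_assignment)
  if (!"residue_number" %in% names(sa) && "sequence_number" %in% names(sa)) {
    sa <- dplyr::rename(sa, residue_number = "sequence_number")
  }
  gen_col <- intersect(c("generic", "struct_based"), names(sa))[1]
  keep <- c("residue_number", "segment", gen_col)
  sa <- sa[, keep[!is.na(keep)]]
  if (!is.na(gen_col) && gen_col != "generic") {
    names(sa)[names(sa) == gen_col] <- "generic"
  }
  out <- dplyr::left_join(out, sa, by = "residue_number")
  coordinate_set(out)
}

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa_three_to_one <- function(x) {
  out <- AA_THREE[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(x) {
  names(AA_THREE)[match(toupper(x), AA_THREE)]
}

#' Pair the atoms common to two coordinate sets
#'
#' Only atoms present in both sets enter an RMSD calculation. Atoms are
#' matched on (generic position, atom name) when both sets carry generic
#' numbering, otherwise on (residue number, atom name); unmatched atoms are
#' dropped and counted.
#'
#' @param a,b `gpcr_coords` tibbles.
#' @return A tibble of paired atoms with columns `key`, `atom`, `segment`,
#'   `xa`,`ya`,`za`, `xb`,`yb`,`zb`; attributes `dropped_a`/`dropped_b`
#'   count unpaired atoms.
#' @export
pair_common_atoms <- function(a, b) {
  a <- coordinate_set(a); b <- coordinate_set(b)
  use_generic <- "generic" %in% names(a) && "generic" %in% names(b) &&
    !all(is.na(a$generic)) && !all(is.na(b$generic))
  keyfun <- function(d) {
    if (use_generic) {
      ifelse(is.na(d$generic), paste0("res", d$residue_number), d$generic)
    } else {
      as.character(d$residue_number)
    }
  }
  a$key <- keyfun(a); b$key <- keyfun(b)
  pairs <- dplyr::inner_join(
    dplyr::select(a, "key", "atom", "segment", xa = "x", ya = "y", za = "z"),
    dplyr::select(b, "key", "atom", xb = "x", yb = "y", zb = "z"),
    by = c("key", "atom"))
  if (!nrow(pairs)) {
    stop("no atoms in common between the two coordinate sets", call. = FALSE)
  }
  attr(pairs, "dropped_a") <- nrow(a) - nrow(pairs)
  attr(pairs, "dropped_b") <- nrow(b) - nrow(pairs)
  pairs
}

# Kabsch least-squares rigid superposition of P onto Q (n x 3 matrices).
# Returns the rotation (applied after centring) and translation; the
# determinant correction enforces a proper rotation (no reflection).
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, center_p = cp, center_q = cq)
}

apply_fit <- function(P, fit) {
  sweep(sweep(P, 2, fit$center_p) %*% t(fit$rotation), 2, fit$center_q, "+")
}

rmsd_of <- function(P, Q) {
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Superpose two coordinate sets and report segment-wise RMSDs
#'
#' Pairs the common atoms of the two sets, computes a single least-squares
#' rigid-body (Kabsch) superposition on the paired 7TM backbone atoms
#' (N, CA, C, O of TM1-TM7), applies that one transform, and evaluates the
#' RMSD of each reporting scope without re-fitting: `7TM_all`,
#' `7TM_backbone`, `ICL1`, `ICL2`, `ECL1`, `ECL2`, `ECL3` and `H8`. Scopes
#' with no paired atoms are omitted.
#'
#' @param a,b `gpcr_coords` tibbles sharing a numbering frame.
#' @return A `gpcr_rmsd_report` tibble: `scope`, `rmsd` (Angstrom),
#'   `n_atoms`.
#' @export
#' @examples
#' toys <- generate_toy_structures(n_residues = 21, displacement = 0,
#'                                 seed = 1)
#' superpose_rmsd(toys$a, toys$b)
superpose_rmsd <- function(a, b) {
  pairs <- pair_common_atoms(a, b)
  bb <- pairs$segment %in% TM_SEGMENTS & pairs$atom %in% BACKBONE_ATOMS
  if (sum(bb) < 3) {
    stop("need at least 3 paired 7TM backbone atoms for superposition, got ",
         sum(bb), call. = FALSE)
  }
  P <- as.matrix(pairs[, c("xa", "ya", "za")])
  Q <- as.matrix(pairs[, c("xb", "yb", "zb")])
  fit <- kabsch_fit(P[bb, , drop = FALSE], Q[bb, , drop = FALSE])
  Pt <- apply_fit(P, fit)

  scope_rows <- list(
    `7TM_all` = pairs$segment %in% TM_SEGMENTS,
    `7TM_backbone` = bb,
    ICL1 = pairs$segment == "ICL1",
    ICL2 = pairs$segment == "ICL2",
    ECL1 = pairs$segment == "ECL1",
    ECL2 = pairs$segment == "ECL2",
    ECL3 = pairs$segment == "ECL3",
    H8 = pairs$segment == "H8"
  )
  out <- purrr::imap(scope_rows, function(sel, scope) {
    sel <- sel & !is.na(sel)
    if (!sum(sel)) return(NULL)
    tibble::tibble(scope = scope,
                   rmsd = rmsd_of(Pt[sel, , drop = FALSE],
                                  Q[sel, , drop = FALSE]),
                   n_atoms = sum(sel))
  })
  out <- dplyr::bind_rows(out)
  out$scope <- factor(out$scope, levels = RMSD_SCOPES)
  out <- dplyr::arrange(out, .data$scope)
  out$scope <- as.character(out$scope)
  class(out) <- unique(c("gpcr_rmsd_report", class(out)))
  out
}

#' Write an RMSD report
#'
#' @param report Output of [superpose_rmsd()].
#' @param path Output path; `.json` selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_rmsd_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tibble::as_tibble(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  }
  invisible(path)
}

#' Plot an RMSD report
#'
#' @param object A `gpcr_rmsd_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of RMSD per segment scope.
#' @method autoplot gpcr_rmsd_report
#' @export
autoplot.gpcr_rmsd_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$scope <- factor(df$scope, levels = RMSD_SCOPES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$rmsd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}
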