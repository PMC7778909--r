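# Synthetic-data generators: contrast alignments with planted functional
# determinants and toy helix coordinate sets. Everything is seeded and
# reproducible; generators emit the same FASTA/TSV/PDB dialects the readers
# consume.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Default column map: n columns spread over TM1-TM7, contiguous indices
# centred on the reference position 50.
default_column_map <- function(n_columns) {
  per <- diff(floor(seq(0, n_columns, length.out = 8)))
  purrr::map_dfr(1:7, function(s) {
    c_ <- per[s]
    if (!c_) return(NULL)
    idx <- seq(50 - (c_ - 1) %/% 2, length.out = c_)
    tibble::tibble(position = sprintf("%dx%02d", s, idx),
                   segment = paste0("TM", s))
  })
}

#' Generate a pair of contrast alignments with planted determinants
#'
#' Builds two synthetic receptor-set alignments sharing one column list.
#' At planted columns, set 1 draws residues uniformly from one property
#' group's members and set 2 from a disjoint group's members, so the column
#' is fully property-separated (conservation difference 100%). At
#' background columns both sets receive the same drawn residue multiset
#' (row-permuted) when the set sizes are equal, so background conservation
#' differences are exactly zero; with unequal sizes, backgrounds are drawn
#' independently from the same distribution and carry sampling noise.
#'
#' @param n_set1,n_set2 Receptors per set.
#' @param n_columns Alignment width.
#' @param planted Tibble with columns `column` (index), `group_set1`,
#'   `group_set2` (taxonomy group labels with disjoint memberships), or
#'   `NULL` for no planted columns.
#' @param background Background residue distribution: `"uniform"` over the
#'   20 amino acids, or a named numeric weight vector.
#' @param seed Random seed; identical seeds give identical alignments.
#' @param columns Optional custom column map (`position`, `segment`) of
#'   `n_columns` rows.
#' @param groups Property-group tibble resolving the planted group labels.
#' @return A list with `aln1`, `aln2` (`gpcr_alignment`) and `truth`
#'   (tibble `column`, `position`, `segment`, `group_set1`, `group_set2`).
#' @export
#' @examples
#' fx <- generate_contrast_alignments(
#'   planted = tibble::tibble(column = c(3, 10),
#'                            group_set1 = "charge_negative@any",
#'                            group_set2 = "charge_positive@any"),
#'   seed = 7)
#' fx$truth
generate_contrast_alignments <- function(n_set1 = 8, n_set2 = 8,
                                         n_columns = 50, planted = NULL,
                                         background = "uniform", seed = 1,
                                         columns = NULL,
                                         groups = aa_property_groups()) {
  if (is.null(columns)) columns <- default_column_map(n_columns)
  columns <- tibble::as_tibble(columns)
  if (nrow(columns) != n_columns) {
    stop("column map must have n_columns rows", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (anyDuplicated(planted$column) ||
        any(planted$column < 1 | planted$column > n_columns)) {
      stop("planted columns must be distinct and within the alignment width",
           call. = FALSE)
    }
    m1 <- groups$members[match(planted$group_set1, groups$group)]
    m2 <- groups$members[match(planted$group_set2, groups$group)]
    if (any(vapply(m1, is.null, logical(1))) ||
        any(vapply(m2, is.null, logical(1)))) {
      stop("unknown planted group label(s)", call. = FALSE)
    }
    overlap <- purrr::map2_lgl(m1, m2, ~length(intersect(.x, .y)) > 0)
    if (any(overlap)) {
      stop("planted groups overlap in membership at column(s): ",
           paste(planted$column[overlap], collapse = ", "), call. = FALSE)
    }
  }
  w <- if (identical(background, "uniform")) {
    stats::setNames(rep(1, 20), AA_CODES)
  } else {
    stopifnot(is.numeric(background), !is.null(names(background)))
    background
  }

  with_seed(seed, {
    m1 <- matrix("-", n_set1, n_columns)
    m2 <- matrix("-", n_set2, n_columns)
    for (j in seq_len(n_columns)) {
      k <- if (is.null(planted)) NA else match(j, planted$column)
      if (!is.na(k)) {
        g1 <- groups$members[[match(planted$group_set1[k], groups$group)]]
        g2 <- groups$members[[match(planted$group_set2[k], groups$group)]]
        m1[, j] <- sample(g1, n_set1, replace = TRUE)
        m2[, j] <- sample(g2, n_set2, replace = TRUE)
      } else {
        col1 <- sample(names(w), n_set1, replace = TRUE, prob = w)
        m1[, j] <- col1
        m2[, j] <- if (n_set2 == n_set1) {
          sample(col1, n_set2, replace = FALSE)
        } else {
          sample(names(w), n_set2, replace = TRUE, prob = w)
        }
      }
    }
    seqs1 <- stats::setNames(apply(m1, 1, paste, collapse = ""),
                             sprintf("set1_r%02d", seq_len(n_set1)))
    seqs2 <- stats::setNames(apply(m2, 1, paste, collapse = ""),
                             sprintf("set2_r%02d", seq_len(n_set2)))
    truth <- if (is.null(planted)) {
      tibble::tibble(column = integer(), position = character(),
                     segment = character(), group_set1 = character(),
                     group_set2 = character())
    } else {
      dplyr::arrange(tibble::tibble(
        column = planted$column,
        position = columns$position[planted$column],
        segment = columns$segment[planted$column],
        group_set1 = planted$group_set1,
        group_set2 = planted$group_set2), .data$column)
    }
    list(aln1 = gpcr_alignment(seqs1, columns),
         aln2 = gpcr_alignment(seqs2, columns),
         truth = truth)
  })
}

#' Ergotamine-style selectivity fixture
#'
#' A synthetic stand-in for the aminergic ergotamine-selectivity case: two
#' receptor sets whose alignments are fully property-separated at the five
#' binding-pocket positions 3x33, 3x36, 5x43, 6x51 and 6x52 and share the
#' background everywhere else, so a signature at a 50% cutoff recovers
#' exactly those positions. The residue content is synthetic; only the
#' statistical structure of the case (planted separated positions among
#' shared columns) is emulated.
#'
#' @param seed Random seed.
#' @param n_set1,n_set2 Receptors per set.
#' @return As [generate_contrast_alignments()].
#' @export
ergotamine_fixture <- function(seed = 1, n_set1 = 8, n_set2 = 8) {
  columns <- dplyr::bind_rows(
    tibble::tibble(position = sprintf("2x%02d", 50:56), segment = "TM2"),
    tibble::tibble(position = sprintf("3x%02d", 29:40), segment = "TM3"),
    tibble::tibble(position = sprintf("4x%02d", 50:56), segment = "TM4"),
    tibble::tibble(position = sprintf("5x%02d", 39:47), segment = "TM5"),
    tibble::tibble(position = sprintf("6x%02d", 48:56), segment = "TM6"),
    tibble::tibble(position = sprintf("7x%02d", 30:35), segment = "TM7")
  )
  planted <- tibble::tibble(
    column = match(c("3x33", "3x36", "5x43", "6x51", "6x52"),
                   columns$position),
    group_set1 = c("aliphatic@any", "charge_negative@any", "hbond_donor@2",
                   "aromatic@5", "hbond_acceptor@3"),
    group_set2 = c("aromatic@5", "charge_positive@any", "aliphatic@3",
                   "aliphatic@any", "aromatic@5")
  )
  generate_contrast_alignments(n_set1 = n_set1, n_set2 = n_set2,
                               n_columns = nrow(columns), planted = planted,
                               seed = seed, columns = columns)
}

# Ideal alpha-helix backbone: 100 degrees and 1.5 Angstrom rise per residue,
# CA radius 2.3 Angstrom; N, C and O placed at fixed rigid offsets so every
# residue contributes the four backbone atoms.
ideal_helix_backbone <- function(n_residues) {
  i <- seq_len(n_residues) - 1
  theta <- i * 100 * pi / 180
  at <- function(r, dtheta, dz) {
    cbind(r * cos(theta + dtheta), r * sin(theta + dtheta), 1.5 * i + dz)
  }
  coords <- rbind(at(1.65, -0.45, -0.95),  # N
                  at(2.30,  0.00,  0.00),  # CA
                  at(2.00,  0.40,  0.65),  # C
                  at(2.45,  0.55,  1.85))  # O
  ord <- order(rep(seq_len(n_residues), 4))
  tibble::tibble(
    residue_number = rep(seq_len(n_residues), each = 4),
    atom = rep(c("N", "CA", "C", "O"), times = n_residues),
    x = coords[ord, 1], y = coords[ord, 2], z = coords[ord, 3]
  )
}

random_rotation <- function() {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  angle <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a pair of toy coordinate sets
#'
#' An ideal helical backbone (N, CA, C, O per residue) and a copy moved by a
#' random rigid rotation plus translation, with an optional per-atom
#' displacement of known magnitude in a random direction. After
#' superposition, zero displacement gives zero RMSD and a uniform
#' displacement `d` gives an RMSD close to (slightly below, because the fit
#' re-optimises) `d`.
#'
#' @param n_residues Number of residues (>= 3).
#' @param displacement Per-atom displacement magnitude in Angstrom applied
#'   to the second set.
#' @param seed Random seed.
#' @param segments Segment label per residue; default splits the residues
#'   contiguously over TM1-TM7.
#' @return A list with `a`, `b` (`gpcr_coords`) and the applied `rotation`
#'   and `translation`.
#' @export
generate_toy_structures <- function(n_residues = 35, displacement = 0,
                                    seed = 1, segments = NULL) {
  if (n_residues < 3) stop("n_residues must be >= 3", call. = FALSE)
  if (is.null(segments)) {
    per <- diff(floor(seq(0, n_residues, length.out = 8)))
    segments <- rep(paste0("TM", 1:7), times = per)
  }
  stopifnot(length(segments) == n_residues)
  with_seed(seed, {
    bb <- ideal_helix_backbone(n_residues)
    res <- sample(AA_CODES, n_residues, replace = TRUE)
    a <- coordinate_set(tibble::tibble(
      residue_number = bb$residue_number,
      residue = res[bb$residue_number],
      atom = bb$atom, x = bb$x, y = bb$y, z = bb$z,
      segment = segments[bb$residue_number]))
    R <- random_rotation()
    t0 <- stats::rnorm(3, sd = 10)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R) +
      matrix(t0, nrow(a), 3, byrow = TRUE)
    if (displacement > 0) {
      dirs <- matrix(stats::rnorm(3 * nrow(a)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      xyz <- xyz + displacement * dirs
    }
    b <- a
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    list(a = a, b = coordinate_set(b), rotation = R, translation = t0)
  })
}

#' Write a coordinate set as a PDB file
#'
#' Emits a standard single-chain PDB file (via bio3d) so the toy structures
#' exercise [read_coordinates()] end-to-end.
#'
#' @param coords A `gpcr_coords` tibble.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_pdb_coords <- function(coords, path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("writing PDB files requires the bio3d package", call. = FALSE)
  }
  xyz <- as.vector(t(as.matrix(coords[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = coords$residue_number,
                   resid = aa_one_to_three(coords$residue),
                   elety = coords$atom,
                   chain = "A",
                   o = rep(1, nrow(coords)), b = rep(0, nrow(coords)))
  invisible(path)
}
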