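# Structure-based multiple alignments indexed by generic positions, and
# per-column conservation / z-scale profiles.

#' Construct a structure-based alignment
#'
#' Builds the alignment container from pre-aligned sequences and a column
#' annotation mapping every alignment column to a generic position and
#' segment. Residues are upper-cased and `"."` gaps normalised to `"-"`;
#' the only residue symbols allowed are the 20 canonical amino acids, `X`
#' (unknown) and the gap.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (names are receptor identifiers).
#' @param columns Tibble with one row per alignment column, columns
#'   `position` (generic position string) and `segment`; an optional
#'   `column` gives the 1-based column index.
#' @return A `gpcr_alignment` object.
#' @export
#' @examples
#' aln <- gpcr_alignment(
#'   c(r1 = "DKL", r2 = "EKI"),
#'   tibble::tibble(position = c("3x32", "3x33", "3x34"), segment = "TM3"))
#' aln
gpcr_alignment <- function(seqs, columns) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("aligned sequences must be named by receptor identifier",
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: record lengths ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  columns <- tibble::as_tibble(columns)
  if (!all(c("position", "segment") %in% names(columns))) {
    stop("column map needs 'position' and 'segment' columns", call. = FALSE)
  }
  if (nrow(columns) != widths[1]) {
    stop("column map has ", nrow(columns), " entries for an alignment of ",
         "width ", widths[1], call. = FALSE)
  }
  columns$column <- seq_len(nrow(columns))
  columns <- columns[, c("column", "position", "segment")]
  if (anyDuplicated(columns$position)) {
    stop("duplicate generic positions in column map", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  mat[mat == "."] <- "-"
  allowed <- c(AA_CODES, "X", "-")
  bad <- which(array(!(mat %in% allowed), dim(mat)), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop("unknown residue symbol '", mat[b[1], b[2]], "' in record '",
         rownames(mat)[b[1]], "' column ", b[2], call. = FALSE)
  }
  structure(list(matrix = mat, columns = columns), class = "gpcr_alignment")
}

#' @export
print.gpcr_alignment <- function(x, ...) {
  cat("<gpcr_alignment> ", nrow(x$matrix), " receptors x ",
      ncol(x$matrix), " generic positions (",
      length(unique(x$columns$segment)), " segments)\n", sep = "")
  invisible(x)
}

#' @export
dim.gpcr_alignment <- function(x) dim(x$matrix)

#' Receptor identifiers of an alignment
#' @param aln A `gpcr_alignment`.
#' @return Character vector.
#' @export
alignment_receptors <- function(aln) rownames(aln$matrix)

#' Read an aligned FASTA plus column map
#'
#' Reads a pre-aligned FASTA (one record per receptor) and a TSV column map
#' with columns `column`, `position`, `segment` covering every alignment
#' column, and assembles a validated [gpcr_alignment()]. Sequences are read
#' with Biostrings when available, otherwise with a plain-text reader.
#'
#' @param fasta Path to the aligned FASTA file.
#' @param column_map Path to the column-map TSV, or an equivalent tibble.
#' @return A `gpcr_alignment` object.
#' @export
read_alignment <- function(fasta, column_map) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(fasta)
    seqs <- stats::setNames(as.character(set), names(set))
  } else {
    seqs <- read_fasta_plain(fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(column_map)) {
    column_map <- readr::read_tsv(column_map, show_col_types = FALSE,
                                  progress = FALSE)
  }
  cm <- tibble::as_tibble(column_map)
  if ("column" %in% names(cm)) cm <- dplyr::arrange(cm, .data$column)
  gpcr_alignment(seqs, cm[, c("position", "segment")])
}

read_fasta_plain <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  id <- cumsum(hdr)
  names_ <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(seqs, names_)
}

#' Write an alignment to FASTA + column-map TSV
#'
#' Emits the same dialects [read_alignment()] consumes, so synthetic
#' alignments exercise the reader end-to-end.
#'
#' @param aln A `gpcr_alignment`.
#' @param fasta,column_map Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_alignment <- function(aln, fasta, column_map = NULL) {
  if (!is.null(fasta)) {
    seqs <- apply(aln$matrix, 1, paste, collapse = "")
    writeLines(paste0(">", names(seqs), "\n", seqs), fasta)
  }
  if (!is.null(column_map)) {
    readr::write_tsv(aln$columns, column_map, progress = FALSE)
  }
  invisible(list(fasta = fasta, column_map = column_map))
}

#' Tidy an alignment into long form
#'
#' @param x A `gpcr_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per receptor x column: `receptor_id`,
#'   `column`, `position`, `segment`, `residue`.
#' @method tidy gpcr_alignment
#' @export
tidy.gpcr_alignment <- function(x, ...) {
  long <- tibble::tibble(
    receptor_id = rep(rownames(x$matrix), times = ncol(x$matrix)),
    column = rep(x$columns$column, each = nrow(x$matrix)),
    residue = as.vector(x$matrix)
  )
  dplyr::left_join(long, x$columns, by = "column")[,
    c("receptor_id", "column", "position", "segment", "residue")]
}

# Per-column residue counts as a symbols x columns matrix.
column_symbol_counts <- function(aln) {
  syms <- c(AA_CODES, "X", "-")
  apply(aln$matrix, 2, function(col) {
    tabulate(factor(col, levels = syms), nbins = length(syms))
  }) -> m
  rownames(m) <- syms
  m
}

#' Property-group conservation per alignment column
#'
#' For every column and property group, the percentage of receptors whose
#' residue at that column belongs to the group. Gap and `X` rows count in
#' the denominator but belong to no group, so an all-gap column scores 0 for
#' every group.
#'
#' @param aln A `gpcr_alignment`.
#' @param groups Property-group tibble; defaults to the 56-group taxonomy.
#' @return A long tibble: `column`, `position`, `segment`, `group`,
#'   `conservation` (percent).
#' @export
group_conservation <- function(aln, groups = aa_property_groups()) {
  counts <- column_symbol_counts(aln)
  member <- group_membership_matrix(groups)
  cons <- 100 * (member %*% counts) / nrow(aln$matrix)
  tibble::tibble(
    column = rep(aln$columns$column, each = nrow(groups)),
    position = rep(aln$columns$position, each = nrow(groups)),
    segment = rep(aln$columns$segment, each = nrow(groups)),
    group = rep(groups$group, times = ncol(counts)),
    conservation = as.vector(cons)
  )
}

#' Per-column alignment profiles
#'
#' Summarises every column of a structure-based alignment: amino-acid
#' frequencies, the consensus property group (highest conservation, ties
#' broken by smallest group cardinality, then taxonomy order), and the mean
#' and standard deviation of the five z-scale descriptors over non-gap
#' residues. All-gap columns are flagged and carry undefined (`NA`) z
#' summaries and no consensus.
#'
#' @param aln A `gpcr_alignment`.
#' @param groups Property-group tibble.
#' @param zscales z-scale tibble, see [aa_zscales()].
#' @return A tibble with one row per column: `column`, `position`,
#'   `segment`, `n_nongap`, `all_gap`, `aa_frequency` (list column of
#'   per-amino-acid percent tibbles), `consensus_group`,
#'   `consensus_conservation`, `z1_mean` ... `z5_mean`, `z1_sd` ...
#'   `z5_sd`.
#' @export
column_profiles <- function(aln, groups = aa_property_groups(),
                            zscales = aa_zscales()) {
  counts <- column_symbol_counts(aln)
  n <- nrow(aln$matrix)
  member <- group_membership_matrix(groups)
  cons <- 100 * (member %*% counts) / n
  zmat <- zscale_matrix(zscales)

  # consensus: order groups by (-conservation, cardinality, taxonomy order)
  consensus <- purrr::map(seq_len(ncol(counts)), function(j) {
    v <- cons[, j]
    if (all(v == 0)) {
      return(tibble::tibble(consensus_group = NA_character_,
                            consensus_conservation = NA_real_))
    }
    ord <- order(-v, groups$cardinality, seq_len(nrow(groups)))[1]
    tibble::tibble(consensus_group = groups$group[ord],
                   consensus_conservation = v[ord])
  })
  consensus <- dplyr::bind_rows(consensus)

  aa_counts <- counts[AA_CODES, , drop = FALSE]
  n_nongap <- colSums(counts[AA_CODES, , drop = FALSE]) +
    counts["X", ]
  zsum <- purrr::map(seq_len(ncol(counts)), function(j) {
    res <- aln$matrix[, j]
    res <- res[res %in% AA_CODES]
    if (!length(res)) {
      m <- rep(NA_real_, 5); s <- rep(NA_real_, 5)
    } else {
      zv <- zmat[res, , drop = FALSE]
      m <- colMeans(zv)
      s <- apply(zv, 2, stats::sd)
    }
    stats::setNames(c(m, s),
                    c(paste0("z", 1:5, "_mean"), paste0("z", 1:5, "_sd")))
  })
  zsum <- dplyr::bind_rows(purrr::map(zsum, as.list))

  freq <- purrr::map(seq_len(ncol(counts)), function(j) {
    tibble::tibble(aa = AA_CODES,
                   frequency = 100 * unname(aa_counts[, j]) / n)
  })

  dplyr::bind_cols(
    aln$columns,
    tibble::tibble(n_nongap = as.integer(n_nongap),
                   all_gap = counts["-", ] == n,
                   aa_frequency = freq),
    consensus,
    zsum
  )
}

#' Write per-column profiles as TSV
#'
#' One row per column x property group at or above the reporting threshold,
#' joined with the column's consensus and z summaries.
#'
#' @param aln A `gpcr_alignment`.
#' @param path Output TSV path.
#' @param threshold Minimum conservation (percent) for a group row to be
#'   reported.
#' @param groups,zscales Taxonomy and z-scale tables.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(aln, path, threshold = 0,
                           groups = aa_property_groups(),
                           zscales = aa_zscales()) {
  prof <- column_profiles(aln, groups, zscales)
  cons <- group_conservation(aln, groups)
  cons <- cons[cons$conservation >= threshold, ]
  out <- dplyr::left_join(
    cons,
    dplyr::select(prof, -"aa_frequency"),
    by = c("column", "position", "segment"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot per-column consensus conservation
#'
#' @param object A `gpcr_alignment`.
#' @param groups,zscales Taxonomy and z-scale tables.
#' @param ... Unused.
#' @return A ggplot object: consensus property-group conservation along the
#'   alignment, faceted by segment.
#' @method autoplot gpcr_alignment
#' @export
autoplot.gpcr_alignment <- function(object, groups = aa_property_groups(),
                                    zscales = aa_zscales(), ...) {
  prof <- column_profiles(object, groups, zscales)
  prof$position <- factor(prof$position, levels = prof$position)
  ggplot2::ggplot(prof,
                  ggplot2::aes(x = .data$position,
                               y = .data$consensus_conservation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(. ~ segment, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "generic position", y = "consensus conservation (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
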