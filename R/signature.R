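# The two-set sequence signature algorithm: per-position property group with
# maximal conservation difference, cutoff and tie-breaking, Welch t-test
# statistics on the five z-scale descriptors, and signature matching.

#' Welch two-sample t-test on z-scale values
#'
#' Two-tailed Welch (unequal variance) t-test used for the per-position
#' z-scale statistics. Degenerate inputs follow fixed conventions: fewer
#' than two values in either sample is not computable; both samples constant
#' with equal means gives p = 1; both constant with distinct means gives
#' p = 0 (complete separation).
#'
#' @param x,y Numeric vectors.
#' @return A list with `mean_difference` (`mean(x) - mean(y)`), `p_value`,
#'   and `computable` (logical).
#' @export
#' @examples
#' zscale_ttest(c(1, 2, 3, 4), c(3, 4, 5, 6))
zscale_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(mean_difference = NA_real_, p_value = NA_real_,
                computable = FALSE))
  }
  md <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(mean_difference = md,
                p_value = if (md == 0) 1 else 0,
                computable = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(mean_difference = md, p_value = unname(tt$p.value), computable = TRUE)
}

#' Compute a two-set sequence signature
#'
#' Contrasts two structure-based alignments sharing the same column list.
#' For each column, the conservation (percent of receptors whose residue is
#' a member) of every property group is computed in both sets; the group
#' with the largest absolute conservation difference is selected, ties
#' broken first by smallest group cardinality (the most distinctive and
#' restrictive group), then by taxonomy order. Columns whose best absolute
#' difference reaches the cutoff form the signature; entries enriched in
#' set 2 carry negative differences and `polarity = "enriched_in_set2"`,
#' representing exclusion properties of set 1. Each entry also carries the
#' per-z-scale Welch t-test contrasting the two sets' descriptor values at
#' that column (`ttest = "sets"`, the default) or the pooled conserved
#' versus non-conserved residues of the selected group
#' (`ttest = "conservation"`); a set with fewer than two non-gap residues
#' leaves the tests not computable for that column.
#'
#' @param aln1,aln2 `gpcr_alignment` objects with identical column lists
#'   (function-positive and function-negative receptor sets).
#' @param groups Property-group tibble; default the 56-group taxonomy.
#' @param zscales z-scale tibble.
#' @param cutoff Minimum absolute conservation difference in percent
#'   (inclusive), in `[0, 100]`.
#' @param ttest Which populations the z-scale t-test contrasts; see above.
#' @return A `gpcr_signature` tibble: `position`, `segment`, `group`,
#'   `base`, `category`, `polarity`, `cons_set1`, `cons_set2`, `difference`
#'   (signed, set 1 minus set 2), `z1_diff` ... `z5_diff`, `z1_p` ...
#'   `z5_p`, `z1_significant` ... `z5_significant` (p <= 0.05), and
#'   `ttest_computable`. Ordered by column.
#' @export
compute_signature <- function(aln1, aln2, groups = aa_property_groups(),
                              zscales = aa_zscales(), cutoff = 50,
                              ttest = c("sets", "conservation")) {
  ttest <- match.arg(ttest)
  if (cutoff < 0 || cutoff > 100) {
    stop("cutoff must be in [0, 100]", call. = FALSE)
  }
  if (!identical(aln1$columns$position, aln2$columns$position)) {
    stop("the two alignments must share an identical column list",
         call. = FALSE)
  }
  member <- group_membership_matrix(groups)
  cons1 <- 100 * (member %*% column_symbol_counts(aln1)) / nrow(aln1$matrix)
  cons2 <- 100 * (member %*% column_symbol_counts(aln2)) / nrow(aln2$matrix)
  diff <- cons1 - cons2
  zmat <- zscale_matrix(zscales)

  rows <- purrr::map(seq_len(ncol(diff)), function(j) {
    d <- diff[, j]
    best <- order(-abs(d), groups$cardinality, seq_len(nrow(groups)))[1]
    if (abs(d[best]) < cutoff || abs(d[best]) == 0) return(NULL)
    r1 <- aln1$matrix[, j]; r1 <- r1[r1 %in% AA_CODES]
    r2 <- aln2$matrix[, j]; r2 <- r2[r2 %in% AA_CODES]
    if (ttest == "sets") {
      tests <- purrr::map(1:5, function(k) {
        zscale_ttest(zmat[r1, k], zmat[r2, k])
      })
    } else {
      pooled <- c(r1, r2)
      inside <- pooled %in% groups$members[[best]]
      tests <- purrr::map(1:5, function(k) {
        zscale_ttest(zmat[pooled[inside], k], zmat[pooled[!inside], k])
      })
    }
    zd <- vapply(tests, `[[`, numeric(1), "mean_difference")
    zp <- vapply(tests, `[[`, numeric(1), "p_value")
    ok <- all(vapply(tests, `[[`, logical(1), "computable"))
    out <- tibble::tibble(
      column = aln1$columns$column[j],
      position = aln1$columns$position[j],
      segment = aln1$columns$segment[j],
      group = groups$group[best],
      base = groups$base[best],
      category = groups$category[best],
      polarity = if (d[best] > 0) "enriched_in_set1" else "enriched_in_set2",
      cons_set1 = unname(cons1[best, j]),
      cons_set2 = unname(cons2[best, j]),
      difference = unname(d[best]),
      ttest_computable = ok
    )
    out[paste0("z", 1:5, "_diff")] <- as.list(zd)
    out[paste0("z", 1:5, "_p")] <- as.list(zp)
    out[paste0("z", 1:5, "_significant")] <- as.list(!is.na(zp) & zp <= 0.05)
    out
  })
  sig <- dplyr::bind_rows(rows)
  if (!nrow(sig)) {
    sig <- tibble::tibble(
      column = integer(), position = character(), segment = character(),
      group = character(), base = character(), category = character(),
      polarity = character(), cons_set1 = double(), cons_set2 = double(),
      difference = double(), ttest_computable = logical())
    sig[paste0("z", 1:5, "_diff")] <- list(double())
    sig[paste0("z", 1:5, "_p")] <- list(double())
    sig[paste0("z", 1:5, "_significant")] <- list(logical())
  }
  new_gpcr_signature(sig, cutoff = cutoff, ttest = ttest,
                     n_set1 = nrow(aln1$matrix), n_set2 = nrow(aln2$matrix))
}

new_gpcr_signature <- function(x, cutoff, ttest, n_set1, n_set2) {
  structure(x, class = c("gpcr_signature", class(tibble::tibble()))) -> out
  attr(out, "cutoff") <- cutoff
  attr(out, "ttest") <- ttest
  attr(out, "n_set1") <- n_set1
  attr(out, "n_set2") <- n_set2
  out
}

#' Summarise a sequence signature
#'
#' @param x A `gpcr_signature`.
#' @param ... Unused.
#' @return A one-row tibble: number of signature positions, cutoff, set
#'   sizes, largest absolute conservation difference, and the count of
#'   significant z-scale entries (p <= 0.05).
#' @method glance gpcr_signature
#' @export
glance.gpcr_signature <- function(x, ...) {
  sig_cols <- paste0("z", 1:5, "_significant")
  tibble::tibble(
    n_positions = nrow(x),
    cutoff = attr(x, "cutoff"),
    n_set1 = attr(x, "n_set1"),
    n_set2 = attr(x, "n_set2"),
    max_abs_difference = if (nrow(x)) max(abs(x$difference)) else NA_real_,
    n_significant_zscales = if (nrow(x)) {
      sum(vapply(sig_cols, function(cn) sum(x[[cn]]), integer(1)))
    } else 0L
  )
}

#' @method tidy gpcr_signature
#' @export
tidy.gpcr_signature <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("position", "group", "difference",
                             paste0("z", 1:5, "_diff"),
                             paste0("z", 1:5, "_p"))],
    cols = dplyr::starts_with("z"),
    names_to = c("zscale", ".value"),
    names_pattern = "z([1-5])_(diff|p)")
  dplyr::rename(long, z_diff = "diff", z_p = "p")
}

#' Match a signature against an alignment
#'
#' Scores every receptor of an alignment against a sequence signature to
#' identify additional receptors that may share the function. A signature
#' position matches when the receptor's residue belongs to the entry's
#' property group; entries enriched in set 2 match when the residue does
#' not. A gap never matches (no evidence).
#'
#' @param sig A `gpcr_signature` (or compatible tibble with `position`,
#'   `group`, `polarity`).
#' @param aln A `gpcr_alignment` containing every signature position.
#' @param groups Property-group tibble used to resolve memberships.
#' @return A tibble sorted by descending score: `receptor_id`,
#'   `matched_positions`, `total_positions`, `score` (percent).
#' @export
match_signature <- function(sig, aln, groups = aa_property_groups()) {
  missing <- setdiff(sig$position, aln$columns$position)
  if (length(missing)) {
    stop("signature position(s) absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(sig)) {
    return(tibble::tibble(receptor_id = alignment_receptors(aln),
                          matched_positions = 0L, total_positions = 0L,
                          score = NA_real_))
  }
  cols <- match(sig$position, aln$columns$position)
  gi <- match(sig$group, groups$group)
  if (anyNA(gi)) {
    stop("unknown signature group(s): ",
         paste(sig$group[is.na(gi)], collapse = ", "), call. = FALSE)
  }
  hits <- vapply(seq_len(nrow(sig)), function(k) {
    res <- aln$matrix[, cols[k]]
    inside <- res %in% groups$members[[gi[k]]]
    if (sig$polarity[k] == "enriched_in_set1") {
      inside
    } else {
      !inside & res %in% c(AA_CODES, "X")  # gaps never match
    }
  }, logical(nrow(aln$matrix)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(aln$matrix))
  matched <- rowSums(hits)
  out <- tibble::tibble(
    receptor_id = alignment_receptors(aln),
    matched_positions = as.integer(matched),
    total_positions = nrow(sig),
    score = 100 * matched / nrow(sig)
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$receptor_id)
}

#' Write / read a signature as TSV or JSON
#'
#' @param sig A `gpcr_signature`.
#' @param path Output path; `.json` selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  flat <- tibble::as_tibble(sig)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      cutoff = attr(sig, "cutoff"),
      ttest = attr(sig, "ttest"),
      n_set1 = attr(sig, "n_set1"),
      n_set2 = attr(sig, "n_set2"),
      entries = flat
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    sig <- tibble::as_tibble(payload$entries)
    new_gpcr_signature(sig, cutoff = payload$cutoff, ttest = payload$ttest,
                       n_set1 = payload$n_set1, n_set2 = payload$n_set2)
  } else {
    sig <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    new_gpcr_signature(sig, cutoff = NA_real_, ttest = NA_character_,
                       n_set1 = NA_integer_, n_set2 = NA_integer_)
  }
}

#' Plot a sequence signature
#'
#' Signed conservation differences per signature position, coloured by
#' polarity (enrichment in set 1 vs set 2) and labelled with the selected
#' property group.
#'
#' @param object A `gpcr_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gpcr_signature
#' @export
autoplot.gpcr_signature <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$position <- factor(df$position, levels = df$position)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$difference,
                                   fill = .data$polarity)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$group),
                       angle = 90, size = 2.6,
                       hjust = ifelse(df$difference >= 0, -0.05, 1.05)) +
    ggplot2::scale_fill_manual(values = c(enriched_in_set1 = "forestgreen",
                                          enriched_in_set2 = "darkorange")) +
    ggplot2::labs(x = "generic position",
                  y = "conservation difference (%)") +
    ggplot2::theme_minimal()
}
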