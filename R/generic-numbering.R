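# Generic residue numbering: sequence-based (Ballesteros-Weinstein style)
# and structure-based schemes, conversion across helix bulges and
# constrictions, and per-receptor numbering tables.

SEGMENT_CODES <- tibble::tibble(
  segment  = c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7", "H8",
               "ICL1", "ECL1", "ICL2", "ECL2", "N-term", "ICL3", "ECL3",
               "C-term"),
  code     = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L,
               12L, 23L, 34L, 45L, NA, NA, NA, NA),
  numbered = c(rep(TRUE, 12), rep(FALSE, 4))
)

#' Receptor segment labels and numeric codes
#'
#' The topology segments of a GPCR: transmembrane helices TM1-TM7, helix 8,
#' the first two intra-/extracellular loops, plus unnumbered segments
#' (termini, ICL3, ECL3). Loop segments carry two-digit codes used in their
#' generic numbers (ICL1 = 12, ECL1 = 23, ICL2 = 34, ECL2 = 45); only
#' segments with `numbered = TRUE` may carry generic residue numbers.
#'
#' @return A tibble with columns `segment`, `code`, `numbered`.
#' @export
segment_codes <- function() SEGMENT_CODES

segment_from_code <- function(code) {
  i <- match(code, SEGMENT_CODES$code)
  SEGMENT_CODES$segment[i]
}

code_from_segment <- function(segment) {
  i <- match(segment, SEGMENT_CODES$segment)
  if (anyNA(i)) {
    stop("unknown segment label(s): ",
         paste(unique(segment[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  code <- SEGMENT_CODES$code[i]
  if (anyNA(code)) {
    stop("segment(s) cannot carry generic numbers: ",
         paste(unique(segment[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

#' Parse generic residue numbers
#'
#' Parses strings such as `"5x43"` (structure-based), `"5.42"`
#' (sequence-based), `"5x461"` (structure-based with a bulge digit) or
#' `"34x51"` (ICL2 loop position). The separator determines the scheme:
#' `"."` is sequence-based, `"x"` (or the typographic multiplication sign)
#' structure-based. Bulge digits are only legal in the structure-based
#' scheme and only in helices.
#'
#' @param x Character vector of generic-position strings.
#' @return A tibble with columns `text` (normalised ASCII form), `scheme`,
#'   `segment`, `index`, `bulge` (integer or `NA`).
#' @export
#' @examples
#' parse_generic(c("5x43", "5.42", "5x461", "34x51"))
parse_generic <- function(x) {
  if (!length(x) || any(!nzchar(x) | is.na(x))) {
    stop("generic position strings must be non-empty", call. = FALSE)
  }
  x_ascii <- gsub("×", "x", x)
  m <- regmatches(x_ascii, regexec("^([0-9]{1,2})([x.])([0-9]{2,3})$", x_ascii))
  bad <- x[vapply(m, length, integer(1)) == 0]
  if (length(bad)) {
    stop("malformed generic position(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seg_code <- as.integer(vapply(m, `[`, character(1), 2))
  sep      <- vapply(m, `[`, character(1), 3)
  digits   <- vapply(m, `[`, character(1), 4)
  segment  <- segment_from_code(seg_code)
  if (anyNA(segment)) {
    stop("unknown segment code in: ",
         paste(x[is.na(segment)], collapse = ", "), call. = FALSE)
  }
  scheme <- ifelse(sep == ".", "sequence_based", "structure_based")
  index <- as.integer(substr(digits, 1, 2))
  bulge <- ifelse(nchar(digits) == 3,
                  as.integer(substr(digits, 3, 3)), NA_integer_)
  if (any(!is.na(bulge) & scheme == "sequence_based")) {
    stop("bulge digit in sequence-based position(s): ",
         paste(x[!is.na(bulge) & scheme == "sequence_based"], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(bulge) & seg_code > 8)) {
    stop("loop positions cannot carry bulge digits: ",
         paste(x[!is.na(bulge) & seg_code > 8], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(scheme = scheme, segment = segment,
                        index = index, bulge = bulge)
  out$text <- format_generic(out)
  dplyr::select(out, "text", "scheme", "segment", "index", "bulge")
}

#' Format generic positions as strings
#'
#' Inverse of [parse_generic()]; always emits ASCII `"x"`.
#'
#' @param pos A tibble with columns `scheme`, `segment`, `index` and
#'   optionally `bulge`.
#' @return Character vector.
#' @export
format_generic <- function(pos) {
  code <- code_from_segment(pos$segment)
  sep <- ifelse(pos$scheme == "sequence_based", ".", "x")
  bulge <- if ("bulge" %in% names(pos)) pos$bulge else NA_integer_
  paste0(code, sep, sprintf("%02d", pos$index),
         ifelse(is.na(bulge), "", as.character(bulge)))
}

#' Bulge and constriction annotations
#'
#' Validates a set of offset annotations. A bulge is a one-residue insertion
#' in a helix relative to the structural consensus (the inserted residue gets
#' a three-digit structure-based number such as `5x461`); a constriction is a
#' one-residue deletion (the structure-based scheme skips the anchored
#' index). On the affected side of the segment, a bulge makes
#' structure-based indices run one ahead of sequence-based indices and a
#' constriction one behind; index 50 is the fixed reference in both schemes,
#' so the affected side is the side of the anchor relative to 50 and
#' `applies_before_anchor` must equal `anchor_index < 50`.
#'
#' @param segment Segment labels (helices only).
#' @param kind `"bulge"` or `"constriction"`.
#' @param anchor_index Structure-based index at which the offset sits: the
#'   parent index of the inserted residue for a bulge, the skipped index for
#'   a constriction.
#' @param applies_before_anchor Logical; which side of the segment shifts.
#' @return A validated tibble of annotations.
#' @export
#' @examples
#' offset_annotations("TM5", "bulge", 46, TRUE)
offset_annotations <- function(segment = character(), kind = character(),
                               anchor_index = integer(),
                               applies_before_anchor = logical()) {
  out <- tibble::tibble(segment = as.character(segment),
                        kind = as.character(kind),
                        anchor_index = as.integer(anchor_index),
                        applies_before_anchor = as.logical(applies_before_anchor))
  validate_offsets(out)
}

validate_offsets <- function(offsets) {
  stopifnot(all(c("segment", "kind", "anchor_index",
                  "applies_before_anchor") %in% names(offsets)))
  bad_kind <- setdiff(unique(offsets$kind), c("bulge", "constriction"))
  if (length(bad_kind)) {
    stop("offset kind must be 'bulge' or 'constriction', got: ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  code_from_segment(offsets$segment)  # errors on unnumbered segments
  if (any(offsets$anchor_index == 50L)) {
    stop("offset anchored at the reference index 50 is not allowed",
         call. = FALSE)
  }
  side <- offsets$anchor_index < 50L
  if (any(side != offsets$applies_before_anchor)) {
    stop("applies_before_anchor inconsistent with anchor side of index 50",
         call. = FALSE)
  }
  dup <- duplicated(offsets[, c("segment", "anchor_index")])
  if (any(dup)) {
    stop("duplicate offset anchors within a segment", call. = FALSE)
  }
  adjacent <- dplyr::group_by(offsets[offsets$kind == "bulge", ], .data$segment)
  adjacent <- dplyr::summarise(
    adjacent,
    adj = any(diff(sort(.data$anchor_index)) == 1L), .groups = "drop")
  if (any(adjacent$adj)) {
    stop("multiple adjacent bulges are unsupported", call. = FALSE)
  }
  offsets
}

#' Curated class A offset annotations
#'
#' The shipped annotation for class A receptors used throughout examples and
#' fixtures: the TM5 bulge (inserted residue 5x461, shifting the
#' extracellular side so that 5x43 corresponds to 5.42) and the TM7
#' constriction on the extracellular side (7x31 corresponds to 7.32).
#'
#' @return An offset-annotation tibble; see [offset_annotations()].
#' @export
class_a_offsets <- function() {
  read_offsets(system.file("extdata", "class_a_offsets.tsv",
                           package = "gpcrsig", mustWork = TRUE))
}

#' Read offset annotations from TSV or YAML
#'
#' @param path File path; `.yml`/`.yaml` files are parsed as a list of
#'   records, anything else as TSV with the columns of
#'   [offset_annotations()].
#' @return A validated offset-annotation tibble.
#' @export
read_offsets <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    out <- purrr::map_dfr(recs, tibble::as_tibble)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE)
  }
  offset_annotations(out$segment, out$kind, out$anchor_index,
                     out$applies_before_anchor)
}

# Materialise the physical-residue label map of one segment: every physical
# residue slot in consensus order with its structure-based label (index +
# optional bulge digit) and its sequence-based index (contiguous, anchored so
# that structure-based 50 == sequence-based 50). Constriction anchors have no
# physical slot; bulges add one.
segment_index_map <- function(segment, offsets, index_range = 1:99) {
  offs <- offsets[offsets$segment == segment, , drop = FALSE]
  bulges <- offs$anchor_index[offs$kind == "bulge"]
  constr <- offs$anchor_index[offs$kind == "constriction"]
  idx <- integer(0)
  blg <- integer(0)
  for (i in index_range) {
    if (!(i %in% constr)) {
      idx <- c(idx, i); blg <- c(blg, NA_integer_)
    }
    if (i %in% bulges) {
      idx <- c(idx, i); blg <- c(blg, 1L)
    }
  }
  ref <- which(idx == 50L & is.na(blg))
  if (length(ref) != 1) {
    stop("segment map must contain the reference index 50 exactly once",
         call. = FALSE)
  }
  tibble::tibble(
    segment = segment,
    struct_index = idx,
    struct_bulge = blg,
    seq_index = 50L + (seq_along(idx) - ref)
  )
}

#' Convert generic numbers between schemes
#'
#' Converts positions between the sequence-based and structure-based schemes
#' given the segment's bulge/constriction annotations. The reference index
#' 50 is fixed under any annotation set; on the affected side of each offset
#' the index shifts by one per offset, and a bulge's inserted residue maps
#' between its three-digit structure-based number (e.g. `5x461`) and an
#' ordinary sequence-based number. Converting a structure-based index that a
#' constriction removes raises a no-counterpart error, as does a bulge digit
#' with no matching annotation.
#'
#' @param pos Character vector of position strings, or a tibble from
#'   [parse_generic()].
#' @param offsets Offset-annotation tibble ([offset_annotations()]); may be
#'   empty.
#' @param to Target scheme, `"structure_based"` or `"sequence_based"`.
#' @return A tibble like [parse_generic()]'s with converted positions.
#' @export
#' @examples
#' convert_generic("5.42", class_a_offsets(), to = "structure_based")$text
#' convert_generic("7x31", class_a_offsets(), to = "sequence_based")$text
convert_generic <- function(pos, offsets = offset_annotations(),
                            to = c("structure_based", "sequence_based")) {
  to <- match.arg(to)
  if (is.character(pos)) pos <- parse_generic(pos)
  offsets <- validate_offsets(offsets)
  from <- setdiff(c("structure_based", "sequence_based"), to)
  if (any(pos$scheme != from)) {
    stop("position scheme(s) do not match the conversion source (",
         from, "): ", paste(pos$text[pos$scheme != from], collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::pmap_dfr(pos, function(text, scheme, segment, index, bulge,
                                       ...) {
    map <- segment_index_map(segment, offsets)
    if (scheme == "sequence_based") {
      row <- which(map$seq_index == index)
      if (length(row) != 1) {
        stop("no structure-based counterpart for ", text, call. = FALSE)
      }
      tibble::tibble(scheme = "structure_based", segment = segment,
                     index = map$struct_index[row],
                     bulge = map$struct_bulge[row])
    } else {
      row <- which(map$struct_index == index &
                     (is.na(bulge) & is.na(map$struct_bulge) |
                        !is.na(bulge) & !is.na(map$struct_bulge) &
                        map$struct_bulge == bulge))
      if (length(row) != 1) {
        stop("no sequence-based counterpart for ", text,
             " under the given annotations", call. = FALSE)
      }
      tibble::tibble(scheme = "sequence_based", segment = segment,
                     index = map$seq_index[row], bulge = NA_integer_)
    }
  })
  out$text <- format_generic(out)
  dplyr::select(out, "text", "scheme", "segment", "index", "bulge")
}

#' Build a per-receptor generic numbering table
#'
#' Assigns sequence-based and structure-based generic numbers to every
#' residue of annotated segments. Within each segment, indices count
#' contiguously outward from the reference residue (index 50) in both
#' directions; bulge residues receive three-digit structure-based numbers
#' and constrictions make the structure-based scheme skip an index. Residues
#' outside annotated segments carry no generic numbers.
#'
#' @param sequence Amino-acid string (canonical sequence).
#' @param boundaries Tibble with columns `segment`, `start`, `end`
#'   (1-based sequence positions, inclusive, non-overlapping, ordered).
#' @param references Tibble with columns `segment`, `ref`: the sequence
#'   position of the residue bearing index 50 in each segment.
#' @param offsets Offset-annotation tibble; default none.
#' @param receptor_id Identifier stored in the `receptor_id` column.
#' @return A tibble with columns `receptor_id`, `sequence_number`,
#'   `residue`, `segment`, `seq_based`, `struct_based` (generic position
#'   strings or `NA`).
#' @export
#' @examples
#' tbl <- build_numbering_table(
#'   "MKTAYIAKQR",
#'   boundaries = tibble::tibble(segment = "TM1", start = 1, end = 10),
#'   references = tibble::tibble(segment = "TM1", ref = 6))
#' tbl$struct_based
build_numbering_table <- function(sequence, boundaries, references,
                                  offsets = offset_annotations(),
                                  receptor_id = "receptor") {
  residues <- strsplit(toupper(sequence), "")[[1]]
  n <- length(residues)
  bad <- setdiff(unique(residues), c(AA_CODES, "X"))
  if (length(bad)) {
    stop("unknown residue symbol(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  boundaries <- dplyr::arrange(tibble::as_tibble(boundaries), .data$start)
  if (any(boundaries$start > boundaries$end) ||
      any(boundaries$start < 1) || any(boundaries$end > n)) {
    stop("segment boundaries outside the sequence", call. = FALSE)
  }
  if (nrow(boundaries) > 1 &&
      any(boundaries$start[-1] <= boundaries$end[-nrow(boundaries)])) {
    overlapping <- boundaries$segment[
      c(FALSE, boundaries$start[-1] <= boundaries$end[-nrow(boundaries)])]
    stop("overlapping segment boundaries: ",
         paste(overlapping, collapse = ", "), call. = FALSE)
  }
  offsets <- validate_offsets(offsets)

  out <- tibble::tibble(
    receptor_id = receptor_id,
    sequence_number = seq_len(n),
    residue = residues,
    segment = NA_character_,
    seq_based = NA_character_,
    struct_based = NA_character_
  )
  for (s in seq_len(nrow(boundaries))) {
    seg <- boundaries$segment[s]
    span <- boundaries$start[s]:boundaries$end[s]
    out$segment[span] <- seg
    ref <- references$ref[match(seg, references$segment)]
    if (is.na(ref)) next  # annotated extent but no reference: unnumbered
    if (ref < boundaries$start[s] || ref > boundaries$end[s]) {
      stop("reference position for ", seg, " lies outside its boundaries",
           call. = FALSE)
    }
    map <- segment_index_map(seg, offsets)
    ref_row <- which(map$seq_index == 50L)
    rows <- ref_row + (span - ref)
    if (any(rows < 1 | rows > nrow(map))) {
      stop("segment ", seg, " extends beyond the representable index range",
           call. = FALSE)
    }
    out$seq_based[span] <- format_generic(tibble::tibble(
      scheme = "sequence_based", segment = seg,
      index = map$seq_index[rows], bulge = NA_integer_))
    out$struct_based[span] <- format_generic(tibble::tibble(
      scheme = "structure_based", segment = seg,
      index = map$struct_index[rows], bulge = map$struct_bulge[rows]))
  }
  dup <- out$struct_based[!is.na(out$struct_based)]
  if (anyDuplicated(dup)) {
    stop("duplicate structure-based numbers assigned: ",
         paste(unique(dup[duplicated(dup)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a numbering table to disk
#'
#' Exports the table of [build_numbering_table()] as TSV or
#' spreadsheet-compatible CSV.
#'
#' @param tbl Numbering-table tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_numbering_table <- function(tbl, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  cols <- c("sequence_number", "residue", "seq_based", "struct_based",
            "segment")
  tbl <- tbl[, c(intersect("receptor_id", names(tbl)), cols)]
  if (format == "tsv") {
    readr::write_tsv(tbl, path, progress = FALSE)
  } else {
    readr::write_csv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a segment annotation sidecar
#'
#' Reads a YAML annotation with per-segment `boundaries` (start/end),
#' `references` (sequence position of index 50) and `offsets`.
#'
#' @param path YAML file path.
#' @return A list with tibbles `boundaries`, `references`, `offsets`.
#' @export
read_segment_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  boundaries <- purrr::map_dfr(y$boundaries, tibble::as_tibble)
  references <- purrr::map_dfr(y$references, tibble::as_tibble)
  offsets <- if (length(y$offsets)) {
    o <- purrr::map_dfr(y$offsets, tibble::as_tibble)
    offset_annotations(o$segment, o$kind, o$anchor_index,
                       o$applies_before_anchor)
  } else {
    offset_annotations()
  }
  list(boundaries = boundaries, references = references, offsets = offsets)
}
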