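#' Identify SNP-like positions from an unlabeled control sample
#'
#' Positions where mismatches recur at high frequency across cells of a
#' no-label control are genomic variants, not conversions, and must be
#' excluded from conversion counting. A position is masked when its read
#' depth is at least 2 and its mismatch rate is strictly greater than 0.5.
#'
#' @param control_mismatches Data frame with columns `contig`, `position`,
#'   `depth`, `mismatches` giving, per genomic position, the total read depth
#'   and the number of mismatch-carrying reads observed in the control.
#' @param min_depth Minimum depth for a position to be maskable.
#' @param min_rate Mismatch rate that must be strictly exceeded.
#'
#' @return A tibble with columns `contig`, `position` (the SNP mask).
#' @examples
#' ctl <- tibble::tibble(contig = "g1", position = 1:3,
#'                       depth = c(3L, 1L, 4L), mismatches = c(2L, 1L, 2L))
#' mask_snp_positions(ctl) # only position 1: rate 0.667 at depth 3
#' @export
mask_snp_positions <- function(control_mismatches, min_depth = 2, min_rate = 0.5) {
  stopifnot(all(c("contig", "position", "depth", "mismatches") %in%
                  names(control_mismatches)))
  if (any(control_mismatches$depth < 0) || any(control_mismatches$mismatches < 0)) {
    stop("depths and mismatch counts must be non-negative")
  }
  if (any(control_mismatches$mismatches > control_mismatches$depth)) {
    stop("mismatch count exceeds depth at some position")
  }
  control_mismatches |>
    dplyr::filter(.data$depth >= min_depth,
                  .data$mismatches / .data$depth > min_rate) |>
    dplyr::distinct(.data$contig, .data$position) |>
    tibble::as_tibble()
}

# Parse "a-b;c-d" interval encodings into a two-column matrix (0-based,
# half-open).
parse_intervals <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
  colnames(m) <- c("start", "end")
  m
}

parse_int_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

parse_conversions <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(position = integer(0), supporting = logical(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    position = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    supporting = vapply(parts, function(p) p[2] == "1", logical(1))
  )
}

#' Read a tagged-read table from TSV
#'
#' The tagged-read table is the upstream hand-off format: one row per aligned
#' read with its cell barcode, UMI, gene, covered intervals (0-based,
#' half-open, `start-end` pairs separated by `;`), per-interval region tags
#' (`exonic`/`intronic`/`ambiguous`), the covered reference-T positions
#' (`t_sites`, `;`-separated) and observed conversion events
#' (`position:flag` pairs, flag 1 = conversion-supporting).
#'
#' @param path Path to a TSV file.
#' @return A tibble with list-columns `intervals` (integer matrices),
#'   `region_tags`, `t_sites` and `conversions` (data frames).
#' @export
read_tagged_reads <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("cell_barcode", "umi", "gene", "intervals", "region_tags",
                  "n_T", "t_sites", "conversions") %in% names(raw)))
  tibble::tibble(
    cell_barcode = raw$cell_barcode,
    umi = raw$umi,
    gene = raw$gene,
    contig = if ("contig" %in% names(raw)) raw$contig else raw$gene,
    intervals = lapply(raw$intervals, parse_intervals),
    region_tags = strsplit(raw$region_tags, ";", fixed = TRUE),
    n_T = as.integer(raw$n_T),
    t_sites = lapply(raw$t_sites, parse_int_list),
    conversions = lapply(raw$conversions, parse_conversions)
  )
}

#' Write a tagged-read table to TSV
#'
#' @param reads Tagged-read tibble as produced by [simulate_read_table()] or
#'   [read_tagged_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tagged_reads <- function(reads, path) {
  enc <- tibble::tibble(
    cell_barcode = reads$cell_barcode,
    umi = reads$umi,
    gene = reads$gene,
    contig = reads$contig,
    intervals = vapply(reads$intervals, function(m) {
      paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")
    }, character(1)),
    region_tags = vapply(reads$region_tags, paste, character(1), collapse = ";"),
    n_T = vapply(reads$t_sites, length, integer(1)),
    t_sites = vapply(reads$t_sites, paste, character(1), collapse = ";"),
    conversions = vapply(reads$conversions, function(d) {
      paste(sprintf("%d:%d", d$position, as.integer(d$supporting)), collapse = ";")
    }, character(1))
  )
  readr::write_tsv(enc, path)
  invisible(path)
}

# TRUE where positions fall inside any row of an interval matrix.
positions_covered <- function(positions, intervals) {
  if (length(positions) == 0) return(logical(0))
  covered <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(intervals))) {
    covered <- covered |
      (positions >= intervals[i, 1] & positions < intervals[i, 2])
  }
  covered
}

# Union of 0-based half-open intervals across reads -> sorted disjoint matrix.
union_intervals <- function(interval_list) {
  m <- do.call(rbind, interval_list)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      j <- nrow(out)
      if (m[i, 1] <= out[j, 2]) {
        out[j, 2] <- max(out[j, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}

merge_one_group <- function(rows, masked_pos) {
  ivals <- union_intervals(rows$intervals)
  t_union <- sort(unique(unlist(rows$t_sites)))
  # Candidate loci: every position where any read observed a mismatch event,
  # minus masked SNP positions.
  ev <- dplyr::bind_rows(rows$conversions)
  loci <- data.frame(position = integer(0), n = integer(0), k = integer(0))
  if (nrow(ev) > 0) {
    pos <- setdiff(sort(unique(ev$position)), masked_pos)
    if (length(pos) > 0) {
      n <- vapply(pos, function(p) {
        sum(vapply(rows$intervals, function(iv) {
          any(p >= iv[, 1] & p < iv[, 2])
        }, logical(1)))
      }, integer(1))
      k <- vapply(pos, function(p) {
        sum(vapply(rows$conversions, function(d) {
          any(d$position == p & d$supporting)
        }, logical(1)))
      }, integer(1))
      loci <- data.frame(position = pos, n = n, k = k)
    }
  }
  tags <- unlist(rows$region_tags)
  status <- classify_splice_status(tags)
  tibble::tibble(
    cell_barcode = rows$cell_barcode[1],
    umi = rows$umi[1],
    gene = rows$gene[1],
    n_T = length(t_union),
    n_reads = nrow(rows),
    merged_length = sum(ivals[, 2] - ivals[, 1]),
    splice_status = status,
    loci = list(loci)
  )
}

#' Merge tagged reads into UMI-level molecules
#'
#' All reads sharing a (cell barcode, UMI) pair originate from one captured
#' transcript; merging collapses their covered positions, so the molecule's
#' observed T count is the number of distinct reference-T positions in the
#' union of intervals. At every position where at least one read observed a
#' mismatch, the merged record stores the read depth `n` (reads covering the
#' position) and the conversion support `k` (reads carrying the conversion),
#' after removing masked SNP positions. Groups whose reads map to more than
#' one gene are dropped with a message: the assignment is ambiguous.
#'
#' @param reads Tagged-read tibble (see [read_tagged_reads()]).
#' @param snp_mask Optional SNP mask tibble from [mask_snp_positions()]; masked
#'   positions are excluded from conversion evidence (matched per contig).
#' @return A molecule tibble with columns `cell_barcode`, `umi`, `gene`,
#'   `n_T`, `n_reads`, `merged_length`, `splice_status` and list-column
#'   `loci` (data frames with `position`, `n`, `k`).
#' @export
merge_reads <- function(reads, snp_mask = NULL) {
  stopifnot(is.data.frame(reads), nrow(reads) > 0)
  key <- paste(reads$cell_barcode, reads$umi, sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  multi_gene <- vapply(groups, function(ix) {
    length(unique(reads$gene[ix])) > 1
  }, logical(1))
  if (any(multi_gene)) {
    message(sum(multi_gene),
            " UMI group(s) mapped to multiple genes and were dropped")
    groups <- groups[!multi_gene]
  }
  mask_by_contig <- if (!is.null(snp_mask) && nrow(snp_mask) > 0) {
    split(snp_mask$position, snp_mask$contig)
  } else {
    list()
  }
  out <- lapply(groups, function(ix) {
    rows <- reads[ix, ]
    masked <- mask_by_contig[[rows$contig[1]]]
    merge_one_group(rows, if (is.null(masked)) integer(0) else masked)
  })
  dplyr::bind_rows(out)
}

#' Splice status of a molecule from its reads' region tags
#'
#' A molecule is `spliced` when every constituent read maps to exonic
#' sequence only, `unspliced` when at least one read touches an intron, and
#' `ambiguous` otherwise (ambiguous molecules are excluded from kinetic
#' estimation downstream).
#'
#' @param region_tags Character vector of per-interval region tags pooled over
#'   the molecule's reads (`"exonic"`, `"intronic"`, `"ambiguous"`).
#' @return One of `"spliced"`, `"unspliced"`, `"ambiguous"`.
#' @examples
#' classify_splice_status(c("exonic", "exonic"))   # spliced
#' classify_splice_status(c("exonic", "intronic")) # unspliced
#' @export
classify_splice_status <- function(region_tags) {
  stopifnot(length(region_tags) > 0)
  if (any(region_tags == "intronic")) return("unspliced")
  if (all(region_tags == "exonic")) return("spliced")
  "ambiguous"
}

#' Write a molecule table to TSV
#'
#' Flat export of a merged molecule tibble: loci are encoded as
#' `position:k/n` triplets separated by `;`.
#'
#' @param molecules Molecule tibble from [merge_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  enc <- molecules |>
    dplyr::mutate(
      k_loci = vapply(.data$loci, function(d) {
        paste(sprintf("%d:%d/%d", d$position, d$k, d$n), collapse = ";")
      }, character(1)),
      loci = NULL
    )
  readr::write_tsv(enc, path)
  invisible(path)
}
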