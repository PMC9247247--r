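# ---------------------------------------------------------------------------
# CDR3 junction decomposition: V-remainder / N1 / D-core / N2 / J-remainder,
# with J ambiguity classes (sequence-identical germline J genes are never
# silently resolved) and V x J usage tallies.
# ---------------------------------------------------------------------------

# maximal common-substring runs between a window of the read and the D core:
# tibble(x_start, x_end [absolute read coords], core_start, len)
.core_runs <- function(sequence, lo, hi, d_core) {
  if (hi < lo) {
    return(tibble(x_start = integer(0), x_end = integer(0),
                  core_start = integer(0), len = integer(0)))
  }
  W <- utf8ToInt(substr(sequence, lo, hi))
  cc <- utf8ToInt(d_core)
  nc <- length(cc)
  R_prev <- integer(nc)
  out <- list()
  eq_prev <- NULL
  eq_rows <- lapply(seq_along(W), function(i) W[i] == cc)
  for (i in seq_along(W)) {
    eq <- eq_rows[[i]]
    R <- ifelse(eq, c(0L, R_prev[-nc]) + 1L, 0L)
    # a run ends where it cannot extend to (i+1, j+1)
    nxt <- if (i < length(W)) c(eq_rows[[i + 1L]][-1L], FALSE) else rep(FALSE, nc)
    ending <- which(R > 0L & !nxt)
    for (j in ending) {
      out[[length(out) + 1L]] <- c(x_end = lo + i - 1L, core_end = j, len = R[j])
    }
    R_prev <- R
  }
  if (length(out) == 0L) {
    return(tibble(x_start = integer(0), x_end = integer(0),
                  core_start = integer(0), len = integer(0)))
  }
  m <- do.call(rbind, out)
  tibble(x_start = m[, "x_end"] - m[, "len"] + 1L, x_end = m[, "x_end"],
         core_start = m[, "core_end"] - m[, "len"] + 1L, len = m[, "len"])
}

#' Decompose the junction of an expressed sequence
#'
#' Chooses the decomposition maximizing total templated nucleotides (V
#' prefix match + J suffix match ending at the constant anchor + D-core
#' substring of at least `min_d_match` nt). Ties are broken towards the
#' longest V match, then the longest J match, then the leftmost D
#' placement; all germline J achieving the chosen match are reported as an
#' ambiguity set. The search is exhaustive: trimming the V or J anchor by
#' more than the D-core length can never pay, so scanning that window below
#' the maximal anchors covers every decomposition. Remaining bases become
#' the non-templated regions `n1`/`n2`; without a D call the middle is one
#' undifferentiated N region. The parts re-concatenate to the observed
#' sequence between the V start and the constant anchor, exactly.
#'
#' @param sequence merged amplicon sequence (starts at the V 5' end).
#' @param v_nt germline V nucleotide sequence (the assigned gene).
#' @param j_tbl tibble of candidate germline J genes: columns `name`, `nt`.
#' @param d_core diversity core sequence(s); first is used.
#' @param c_pos 1-based position of the constant anchor in `sequence`.
#' @param min_d_match minimum D-core match length to call D.
#' @param min_j_anchor minimum J match; below it the read is unresolvable.
#' @return list of class `trb_junction`: `v_trim`, `n1`, `d_call`,
#'   `d5_trim`, `d3_trim`, `n2`, `j_call` (character vector), `j_trim`,
#'   `v_match`, `j_match`, `junction_nt`, `junction_aa`, `ok` and, when
#'   `ok` is `FALSE`, `reason`.
#' @export
decompose_junction <- function(sequence, v_nt, j_tbl, d_core, c_pos,
                               min_d_match = 4L, min_j_anchor = 8L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, c_pos >= 2L)
  d_core <- d_core[1]
  m_v <- .common_prefix(sequence, v_nt)
  upto_c <- substr(sequence, 1L, c_pos - 1L)
  raw <- vapply(j_tbl$nt, function(j) .common_suffix(upto_c, j), integer(1))
  mj_abs <- if (length(raw)) max(raw) else 0L
  if (min(mj_abs, nchar(upto_c) - max(0L, m_v - nchar(d_core))) < min_j_anchor) {
    return(structure(list(ok = FALSE, reason = "no_j_anchor",
                          v_match = m_v, j_match = mj_abs),
                     class = "trb_junction"))
  }
  back <- nchar(d_core)
  va_range <- seq.int(m_v, max(0L, m_v - back))
  lo0 <- max(0L, m_v - back) + 1L
  hi0 <- c_pos - 1L - min_j_anchor
  runs <- .core_runs(sequence, lo0, hi0, d_core)
  dl_of <- function(lo, hi) {
    if (nrow(runs) == 0L || hi < lo) return(0L)
    ov <- pmin(runs$x_end, hi) - pmax(runs$x_start, lo) + 1L
    ov <- pmax(ov, 0L)
    if (max(ov) < min_d_match) 0L else max(ov)
  }
  best <- NULL
  for (va in va_range) {
    mj_top <- min(mj_abs, nchar(upto_c) - va)
    if (mj_top < min_j_anchor) next
    for (mj in seq.int(mj_top, max(min_j_anchor, mj_top - back))) {
      dl <- dl_of(va + 1L, c_pos - 1L - mj)
      tot <- va + mj + dl
      if (is.null(best) || tot > best$tot) {
        best <- list(tot = tot, va = va, mj = mj, dl = dl)
      }
      # ties resolve towards larger va then larger mj: the scan order
      # (va descending, mj descending) visits those first
    }
  }
  if (is.null(best)) {
    return(structure(list(ok = FALSE, reason = "no_j_anchor",
                          v_match = m_v, j_match = mj_abs),
                     class = "trb_junction"))
  }
  v_end <- best$va
  m <- best$mj
  jc <- which(raw >= m)
  j_start <- c_pos - m
  middle <- if (j_start - 1L >= v_end + 1L)
    substr(sequence, v_end + 1L, j_start - 1L) else ""
  if (best$dl >= min_d_match) {
    lo <- v_end + 1L; hi <- j_start - 1L
    ov <- pmin(runs$x_end, hi) - pmax(runs$x_start, lo) + 1L
    cand <- which(ov == best$dl)
    cs <- pmax(runs$x_start[cand], lo)
    pickk <- cand[order(cs, runs$core_start[cand])][1]
    x_s <- max(runs$x_start[pickk], lo)
    core_s <- runs$core_start[pickk] + (x_s - runs$x_start[pickk])
    n1 <- substr(sequence, v_end + 1L, x_s - 1L)
    d_part <- substr(sequence, x_s, x_s + best$dl - 1L)
    n2 <- substr(sequence, x_s + best$dl, j_start - 1L)
    d_call <- "D"
    d5 <- core_s - 1L
    d3 <- nchar(d_core) - (core_s - 1L) - best$dl
  } else {
    n1 <- middle; d_part <- ""; n2 <- ""
    d_call <- NA_character_; d5 <- NA_integer_; d3 <- NA_integer_
  }
  # reconstruction invariant: parts re-concatenate to the observed read
  stopifnot(identical(paste0(substr(sequence, 1L, v_end), n1, d_part, n2,
                             substr(sequence, j_start, c_pos - 1L)),
                      substr(sequence, 1L, c_pos - 1L)))
  jn_start <- max(1L, v_end - 2L)
  jn_end <- min(nchar(sequence), j_start + 2L)
  junction_nt <- substr(sequence, jn_start, jn_end)
  junction_aa <- if ((jn_start - 1L) %% 3L == 0L)
    translate_nt(junction_nt) else NA_character_
  structure(list(
    ok = TRUE,
    v_trim = nchar(v_nt) - v_end,
    v_match = v_end,
    n1 = n1,
    d_call = d_call, d5_trim = d5, d3_trim = d3, d_part = d_part,
    n2 = n2,
    j_call = j_tbl$name[jc], j_trim = nchar(j_tbl$nt[jc[1]]) - m,
    j_match = m, j_start = j_start,
    junction_nt = junction_nt, junction_aa = junction_aa
  ), class = "trb_junction")
}

#' Decompose all assigned clonotypes
#'
#' Runs [decompose_junction()] on each non-novel clonotype with a constant
#' call, against the J genes of its region (both transcriptional units:
#' inverted identical duplicates make orientation undecidable) and the
#' region's assigned first V gene.
#'
#' @param clonotypes tibble from [assign_germline()].
#' @param annotation a `trb_annotation`.
#' @param d_core diversity core sequence; defaults to the annotation's D.
#' @param min_d_match,min_j_anchor see [decompose_junction()].
#' @return `clonotypes` with junction columns (`v_trim`, `np1_length`,
#'   `n1`, `d_call`, `n2`, `np2_length`, `j_call`, `j_trim`,
#'   `junction`, `junction_aa`, `junction_ok`).
#' @export
decompose_all <- function(clonotypes, annotation, d_core = NULL,
                          min_d_match = 4L, min_j_anchor = 8L) {
  segs <- annotation$segments
  if (is.null(d_core)) {
    dseq <- segs$nt[segs$segment_type == "D"]
    if (length(dseq) == 0L) stop("no D segment in annotation and no d_core given")
    d_core <- dseq[1]
  }
  v_by_name <- setNames(segs$nt, segs$name)
  out <- clonotypes
  out$junction_ok <- FALSE
  out$v_trim <- NA_integer_; out$j_trim <- NA_integer_
  out$n1 <- NA_character_; out$n2 <- NA_character_
  out$np1_length <- NA_integer_; out$np2_length <- NA_integer_
  out$d_call <- NA_character_
  out$j_call <- NA_character_; out$j_call_list <- vector("list", nrow(out))
  out$junction <- NA_character_; out$junction_aa <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (out$novel[i] || is.na(out$c_call[i]) || is.na(out$c_pos[i])) next
    region <- out$c_call[i]
    j_tbl <- segs[segs$segment_type == "J" & segs$region_label == region,
                  c("name", "nt")]
    if (nrow(j_tbl) == 0L) next
    vnm <- out$v_call_list[[i]][1]
    dec <- decompose_junction(out$sequence[i], v_by_name[[vnm]], j_tbl,
                              d_core, out$c_pos[i],
                              min_d_match = min_d_match,
                              min_j_anchor = min_j_anchor)
    if (!dec$ok) next
    out$junction_ok[i] <- TRUE
    out$v_trim[i] <- dec$v_trim; out$j_trim[i] <- dec$j_trim
    out$n1[i] <- dec$n1; out$n2[i] <- dec$n2
    out$np1_length[i] <- nchar(dec$n1); out$np2_length[i] <- nchar(dec$n2)
    out$d_call[i] <- dec$d_call
    out$j_call_list[[i]] <- sort(dec$j_call)
    out$j_call[i] <- paste(sort(dec$j_call), collapse = ",")
    out$junction[i] <- dec$junction_nt; out$junction_aa[i] <- dec$junction_aa
  }
  out
}

#' J identity classes of an annotation
#'
#' Germline J genes with byte-identical nucleotide sequence are
#' indistinguishable in transcripts; each equivalence class gets a label
#' joining its member names with `/`.
#'
#' @param annotation a `trb_annotation`.
#' @return tibble `name`, `class` (one row per J gene).
#' @export
j_identity_classes <- function(annotation) {
  jt <- annotation$segments[annotation$segments$segment_type == "J", ]
  if (nrow(jt) == 0L) return(tibble(name = character(0), class = character(0)))
  cls <- vapply(split(jt$name, paste(jt$region_label, jt$nt)), function(nms)
    paste(sort(nms), collapse = "/"), character(1))
  key <- paste(jt$region_label, jt$nt)
  tibble(name = jt$name, class = unname(cls[key]))
}

#' Tally J usage per V gene with ambiguity classes
#'
#' Read-support sums per (V call, J ambiguity class); classes are the
#' equivalence classes of identical germline J sequences and are never
#' silently resolved to a single gene.
#'
#' @param clonotypes tibble from [decompose_all()].
#' @param annotation a `trb_annotation` (for the identity classes).
#' @return tibble `v_call`, `j_class`, `count`.
#' @export
tally_j_usage <- function(clonotypes, annotation) {
  cls <- j_identity_classes(annotation)
  cls_of <- setNames(cls$class, cls$name)
  ok <- which(clonotypes$junction_ok)
  if (length(ok) == 0L) {
    return(tibble(v_call = character(0), j_class = character(0),
                  count = integer(0)))
  }
  rows <- tibble(
    v_call = clonotypes$v_call[ok],
    j_class = vapply(clonotypes$j_call_list[ok], function(js) {
      cl <- unique(unname(cls_of[js]))
      paste(sort(cl), collapse = ";")
    }, character(1)),
    count = clonotypes$count[ok]
  )
  out <- dplyr::summarise(dplyr::group_by(rows, v_call, j_class),
                          count = sum(count), .groups = "drop")
  out[order(out$v_call, out$j_class), ]
}
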