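# Core half-sib family resolution engine.
#
# State representation: one character matrix per haploblock with two rows per
# pedigree individual (maternal haplotype first, then paternal) in pedigree
# order, one column per retained marker, NA = missing. A half-sib family is
# described by the two rows holding the shared parent's own alleles and the
# rows holding the parent-derived slots of its offspring.

.fmt_allele <- function(v) paste(ifelse(is.na(v), "-", v), collapse = "")

#' Resolve one half-sib family
#'
#' Applies the family-level decision chain to one half-sib family: group the
#' parent-derived progeny alleles, confront the group consensuses with the two
#' parental alleles, and impute, update or reject alleles so that parent and
#' progeny become consistent. Large families (at least
#' `homozygous_family_min` members) whose progeny alleles fall into a single
#' group are resolved under the presumption that the parent is homozygous;
#' smaller families and multi-group families are resolved conservatively,
#' merging a progeny allele with a parental allele only when the progeny data
#' conflict with the other parental allele (which proves which gamete was
#' received). Every mutation is logged.
#'
#' @param state Character matrix (haplotype rows x markers, `NA` = missing).
#' @param family A list with `parent_rows` (length-2 integer: rows of the
#'   parent's maternal and paternal haplotype), `member_rows` (integer vector
#'   of parent-derived progeny slot rows), and optionally `parent_id`,
#'   `member_labels`, `member_keys` (deterministic grouping tie-break keys)
#'   and `block_id`.
#' @param params An [hb_params()] object.
#'
#' @return A list with the updated `state`, logical `changed`, and a
#'   `diagnostics` data.frame (columns `block_id`, `subject`, `event`,
#'   `detail`).
#' @export
resolve_family <- function(state, family, params) {
  pr <- family$parent_rows
  mr <- family$member_rows
  K <- ncol(state)
  miss <- rep(NA_character_, K)
  blk <- if (is.null(family$block_id)) NA_character_ else family$block_id
  parent_id <- if (is.null(family$parent_id)) paste0("row", pr[1L]) else family$parent_id
  mlab <- if (is.null(family$member_labels)) paste0("row", mr) else family$member_labels
  mkeys <- if (is.null(family$member_keys)) sprintf("%06d", seq_along(mr)) else family$member_keys

  state0 <- state
  recs <- list()
  set_row <- function(row, new, subject, event = NULL) {
    old <- state[row, ]
    if (identical(unname(old), unname(new))) return(invisible(NULL))
    state[row, ] <<- new
    if (is.null(event)) {
      event <- if (all(is.na(old))) "IMPUTED"
      else if (all(is.na(new))) "SET_MISSING"
      else if (any(!is.na(old) & is.na(new))) "MARKER_DATA_DELETED"
      else "UPDATED"
    }
    recs[[length(recs) + 1L]] <<- c(
      subject, event, paste0(.fmt_allele(old), " -> ", .fmt_allele(new)))
    invisible(NULL)
  }
  finish <- function() {
    d <- if (length(recs)) {
      m <- do.call(rbind, recs)
      structure(list(block_id = rep(blk, nrow(m)), subject = m[, 1L],
                     event = m[, 2L], detail = m[, 3L]),
                class = "data.frame", row.names = seq_len(nrow(m)))
    } else .empty_diag_df
    list(state = state, changed = !identical(state0, state), diagnostics = d)
  }
  # Data of an ambiguous or unsupported slot are treated as missing, except
  # marker values transmitted regardless of gamete (parents observed + equal).
  obligate_mask <- function() {
    p1 <- state[pr[1L], ]; p2 <- state[pr[2L], ]
    keep <- !is.na(p1) & !is.na(p2) & p1 == p2
    out <- rep(NA_character_, K)
    out[keep] <- p1[keep]
    out
  }
  if (length(mr) == 0L) return(finish())

  P1 <- state[pr[1L], ]; P2 <- state[pr[2L], ]

  if (!anyNA(P1) && identical(unname(P1), unname(P2))) {
    # Parent homozygous with a fully known allele: every transmitted gamete
    # must equal it exactly; conflicting progeny data are suspect.
    for (j in seq_along(mr)) {
      m <- state[mr[j], ]
      if (.conflicts(m, P1)) set_row(mr[j], miss, mlab[j], "SET_MISSING")
      else set_row(mr[j], P1, mlab[j])
    }
    return(finish())
  }

  grp <- .group_rows(state[mr, , drop = FALSE], mkeys)
  gid <- grp$gid
  cons <- grp$consensus
  G <- length(cons)
  big <- length(mr) >= params$homozygous_family_min

  plab <- paste0(parent_id, " allele ", 1:2)

  if (G == 1L && big) {
    # Single allele group in a large family: parent presumed homozygous.
    C <- cons[[1L]]
    for (i in 1:2) {
      if (.conflicts(state[pr[i], ], C))
        set_row(pr[i], miss, plab[i], "ALLELE_REJECTED")
    }
    P1 <- state[pr[1L], ]; P2 <- state[pr[2L], ]
    U <- if (.conflicts(P1, P2)) C else allele_consensus(list(P1, P2, C))
    set_row(pr[1L], U, plab[1L])
    set_row(pr[2L], U, plab[2L])
    for (j in seq_along(mr)) {
      g <- gid[j]
      if (!is.na(g) && g > 0L) set_row(mr[j], U, mlab[j])
      else if (!is.na(g) && g == 0L) set_row(mr[j], U, mlab[j])
      else if (!.conflicts(state[mr[j], ], U)) set_row(mr[j], U, mlab[j])
    }
  } else if (G == 1L) {
    # Single group, small family: homozygosity cannot be presumed.
    C <- cons[[1L]]
    support <- sum(!is.na(gid) & gid > 0L)
    if (.conflicts(P1, C) && .conflicts(P2, C)) {
      # both parental alleles conflict with the progeny: whichever side has
      # less weight is suspect — parents are rejected only when the progeny
      # group is large enough to outvote them, else the conflicting progeny
      # data are removed by the consistency enforcement below
      if (support >= params$min_group_support) {
        set_row(pr[1L], miss, plab[1L], "ALLELE_REJECTED")
        set_row(pr[2L], miss, plab[2L], "ALLELE_REJECTED")
      }
    } else {
      grouped <- which(!is.na(gid) & gid > 0L)
      S1 <- S2 <- integer(0)
      for (j in grouped) {
        m <- state[mr[j], ]
        q1 <- .conflicts(m, P1); q2 <- .conflicts(m, P2)
        if (q2 && !q1) S1 <- c(S1, j)
        else if (q1 && !q2) S2 <- c(S2, j)
      }
      if (length(S1)) {
        U1 <- allele_consensus(c(list(P1), lapply(mr[S1], function(r) state[r, ])))
        set_row(pr[1L], U1, plab[1L])
        for (j in S1) set_row(mr[j], U1, mlab[j])
      }
      if (length(S2)) {
        U2 <- allele_consensus(c(list(P2), lapply(mr[S2], function(r) state[r, ])))
        set_row(pr[2L], U2, plab[2L])
        for (j in S2) set_row(mr[j], U2, mlab[j])
      }
    }
  } else if (G >= 2L) {
    # Parent treated as heterozygous; at most two groups can be real.
    if (G > 2L) {
      obs_cons <- vapply(cons, function(v) sum(!is.na(v)), integer(1))
      first_member <- vapply(seq_len(G), function(g)
        min(which(!is.na(gid) & gid == g)), integer(1))
      sizes <- vapply(seq_len(G), function(g) sum(gid == g, na.rm = TRUE), integer(1))
      keep <- order(-sizes, -obs_cons, first_member)[1:2]
      om <- obligate_mask()
      for (j in which(!is.na(gid) & gid > 0L & !(gid %in% keep)))
        set_row(mr[j], om, mlab[j],
                if (all(is.na(om))) "SET_MISSING" else NULL)
      cons <- cons[keep]
      gid <- match(gid, keep)          # dropped groups -> NA (now inactive)
      gid[is.na(gid) & rowSums(!is.na(state[mr, , drop = FALSE])) == 0L] <- 0L
    }
    C <- cons
    # Match each parental allele to the unique group consensus it overlaps.
    match_g <- c(NA_integer_, NA_integer_)
    slot_free <- c(TRUE, TRUE)          # may receive a promoted consensus
    for (i in 1:2) {
      Pi <- state[pr[i], ]
      if (all(is.na(Pi))) next
      r1 <- allele_compare(Pi, C[[1L]]); r2 <- allele_compare(Pi, C[[2L]])
      if (r1 == "incompatible" && r2 == "incompatible") {
        set_row(pr[i], miss, plab[i], "ALLELE_REJECTED")
      } else if (r1 == "compatible" && r2 == "compatible") {
        slot_free[i] <- FALSE           # ambiguous: leave undecided this round
      } else if (r1 == "compatible") {
        match_g[i] <- 1L; slot_free[i] <- FALSE
      } else if (r2 == "compatible") {
        match_g[i] <- 2L; slot_free[i] <- FALSE
      }                                 # disjoint with both: slot stays free
    }
    if (!is.na(match_g[1L]) && identical(match_g[1L], match_g[2L])) {
      match_g[2L] <- NA_integer_        # both claim one group: keep the first
      slot_free[2L] <- FALSE
    }
    for (i in 1:2) {
      g <- match_g[i]
      if (is.na(g)) next
      Pi <- state[pr[i], ]
      other <- state[pr[3L - i], ]
      S <- integer(0)
      for (j in which(!is.na(gid) & gid == g)) {
        m <- state[mr[j], ]
        if (.conflicts(m, other) && !.conflicts(m, Pi)) S <- c(S, j)
      }
      U <- allele_consensus(c(list(Pi), lapply(mr[S], function(r) state[r, ])))
      set_row(pr[i], U, plab[i])
      for (j in S) set_row(mr[j], U, mlab[j])
    }
    for (g in 1:2) {
      if (g %in% match_g) next
      members <- which(!is.na(gid) & gid == g)
      support <- length(members)
      if (support < params$min_group_support) {
        # too small to promote; genuinely conflicting members are cleaned by
        # the consistency enforcement below, the rest left for a later pass
        next
      }
      # a slot can only receive a consensus its current data do not conflict
      # with (a disjoint or empty slot qualifies, a contradicting one not)
      candidates <- which(slot_free &
                            vapply(1:2, function(i)
                              !.conflicts(state[pr[i], ], C[[g]]), logical(1)))
      if (length(candidates)) {
        i <- candidates[1L]
        other <- state[pr[3L - i], ]
        S <- members[vapply(members, function(j)
          .conflicts(state[mr[j], ], other), logical(1))]
        if (length(S) >= params$min_group_support) {
          U <- allele_consensus(c(list(state[pr[i], ]),
                                  lapply(mr[S], function(r) state[r, ])))
          set_row(pr[i], U, plab[i])
          for (j in S) set_row(mr[j], U, mlab[j])
          slot_free[i] <- FALSE
          match_g[i] <- g
        }
      }
    }
    # Ungrouped alleles are ambiguous between the two groups: treat as
    # missing, keeping only marker values obligate under both parental alleles.
    om <- obligate_mask()
    for (j in which(is.na(gid))) {
      m <- state[mr[j], ]
      if (any(!is.na(m)) && !identical(unname(m), unname(om)))
        set_row(mr[j], om, mlab[j], if (all(is.na(om))) "SET_MISSING" else NULL)
    }
  }
  # G == 0: all progeny slots entirely missing. The homozygous fully-known
  # parent case was handled above; otherwise nothing can be inferred.

  # Consistency enforcement: a progeny slot conflicting with both (current)
  # parental alleles cannot have been transmitted; its data are suspect.
  P1f <- state[pr[1L], ]; P2f <- state[pr[2L], ]
  for (j in seq_along(mr)) {
    m <- state[mr[j], ]
    if (any(!is.na(m)) && .conflicts(m, P1f) && .conflicts(m, P2f))
      set_row(mr[j], miss, mlab[j], "SET_MISSING")
  }
  # Positions where both parental alleles agree are transmitted regardless of
  # which gamete was received: impute them into missing progeny positions.
  agreed <- !is.na(P1f) & !is.na(P2f) & P1f == P2f
  if (any(agreed)) {
    for (j in seq_along(mr)) {
      m <- state[mr[j], ]
      fill <- agreed & is.na(m)
      if (any(fill)) {
        m[fill] <- P1f[fill]
        set_row(mr[j], m, mlab[j])
      }
    }
  }
  finish()
}

.state_digest <- function(state) {
  paste(ifelse(is.na(state), "\x02", state), collapse = "\x01")
}

#' Iterate half-sib family resolution for one haploblock
#'
#' Repeats passes over all half-sib families (largest first; changes take
#' effect immediately within a pass) until a full pass makes no change
#' (`CONVERGED`), a previously seen configuration recurs (`CYCLE_CONVERGED`;
#' the recurring configuration is returned, after a final consistency sweep
#' that blanks progeny slots conflicting with both parental alleles), or
#' `max_iter` passes elapse (`MAX_ITER`; all genotypes for the block are set
#' missing).
#'
#' @param state Character matrix (haplotype rows x markers, `NA` = missing).
#' @param families List of family descriptors as for [resolve_family()],
#'   ordered by decreasing size.
#' @param params An [hb_params()] object.
#'
#' @return A list with `state`, `status` (one of `"CONVERGED"`,
#'   `"CYCLE_CONVERGED"`, `"MAX_ITER"`), `iterations`, and `diagnostics`.
#' @export
assign_block <- function(state, families, params = hb_params()) {
  recs <- list()
  it <- 0L
  blk <- if (length(families) && !is.null(families[[1L]]$block_id))
    families[[1L]]$block_id else NA_character_

  # blank progeny slots conflicting with both parental alleles: the
  # family-level enforcement applied at pass level, so that every end-of-pass
  # configuration is parent-offspring consistent
  sweep_conflicts <- function(state) {
    changed <- FALSE
    for (fam in families) {
      p1 <- state[fam$parent_rows[1L], ]; p2 <- state[fam$parent_rows[2L], ]
      for (j in seq_along(fam$member_rows)) {
        m <- state[fam$member_rows[j], ]
        if (any(!is.na(m)) && .conflicts(m, p1) && .conflicts(m, p2)) {
          state[fam$member_rows[j], ] <- NA_character_
          changed <- TRUE
          recs[[length(recs) + 1L]] <<- data.frame(
            block_id = blk,
            subject = if (is.null(fam$member_labels))
              paste0("row", fam$member_rows[j]) else fam$member_labels[j],
            event = "SET_MISSING",
            detail = "slot conflicting with both parental alleles blanked at end of pass",
            stringsAsFactors = FALSE)
        }
      }
    }
    list(state = state, changed = changed)
  }

  one_pass <- function(state) {
    changed_any <- FALSE
    for (fam in families) {
      res <- resolve_family(state, fam, params)
      state <- res$state
      if (res$changed) changed_any <- TRUE
      if (nrow(res$diagnostics)) recs[[length(recs) + 1L]] <<- res$diagnostics
    }
    sw <- sweep_conflicts(state)
    list(state = sw$state, changed = changed_any || sw$changed)
  }

  status <- "MAX_ITER"
  seen <- .state_digest(state)
  repeat {
    if (it >= params$max_iter) { status <- "MAX_ITER"; break }
    it <- it + 1L
    p <- one_pass(state)
    state <- p$state
    if (!p$changed) { status <- "CONVERGED"; break }
    d <- .state_digest(state)
    if (d %in% seen) { status <- "CYCLE_CONVERGED"; break }
    seen <- c(seen, d)
  }

  if (status == "MAX_ITER") {
    state[] <- NA_character_
    recs[[length(recs) + 1L]] <- data.frame(
      block_id = blk, subject = NA_character_, event = "NON_CONVERGENCE",
      detail = sprintf("no convergence after %d iterations; all genotypes set missing", it),
      stringsAsFactors = FALSE)
  }
  diagnostics <- if (length(recs)) do.call(rbind, recs) else .empty_diag()
  rownames(diagnostics) <- NULL
  list(state = state, status = status, iterations = it, diagnostics = diagnostics)
}
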