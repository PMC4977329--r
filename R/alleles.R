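#' Compare two haploblock alleles
#'
#' A haploblock allele is the vector of marker allele codes over one block's
#' markers, with `NA` for missing calls. Two alleles are *incompatible* if
#' they carry different observed codes at some marker; *compatible* if they
#' never conflict and share at least one marker where both are observed and
#' equal; *disjoint* if no marker is observed in both.
#'
#' @param a,b Character vectors of equal length; `NA` = missing.
#' @return One of `"compatible"`, `"incompatible"`, `"disjoint"`.
#' @examples
#' allele_compare(c("1","0","1","1","0","0"), c("1","0","1",NA,NA,NA))
#' @export
allele_compare <- function(a, b) {
  if (length(a) != length(b))
    stop("alleles must have equal length", call. = FALSE)
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) return("disjoint")
  if (any(a[both] != b[both])) return("incompatible")
  "compatible"
}

# TRUE iff a and b carry different observed codes at some position.
.conflicts <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  any(a[both] != b[both])
}

#' Consensus of mutually non-conflicting haploblock alleles
#'
#' Positionwise union of observed codes: wherever at least one allele has an
#' observed value, that value is used; missing only where all inputs are
#' missing. The inputs must be pairwise non-incompatible (no two observed,
#' differing codes at any position); conflicting inputs are a caller error.
#'
#' @param alleles A non-empty list of equal-length character vectors
#'   (`NA` = missing).
#' @return A single character vector of the same length.
#' @examples
#' allele_consensus(list(c("1",NA), c(NA,"0")))
#' @export
allele_consensus <- function(alleles) {
  if (!length(alleles)) stop("need at least one allele", call. = FALSE)
  m <- do.call(rbind, alleles)
  out <- rep(NA_character_, ncol(m))
  for (k in seq_len(ncol(m))) {
    v <- unique(m[, k][!is.na(m[, k])])
    if (length(v) > 1L)
      stop("conflicting alleles passed to allele_consensus (position ", k, ")",
           call. = FALSE)
    if (length(v)) out[k] <- v
  }
  out
}

# Internal grouping on a members x markers character matrix. Returns integer
# group id per row (NA = ungrouped, 0 = all-missing) plus the consensus
# matrix. `ord_keys` supplies the tie-break ordering key per row.
.group_rows <- function(mat, ord_keys = NULL) {
  n <- nrow(mat)
  K <- ncol(mat)
  obs <- rowSums(!is.na(mat))
  gid <- integer(n)                      # 0 = all-missing until assigned
  if (is.null(ord_keys)) ord_keys <- sprintf("%06d", seq_len(n))
  active <- which(obs > 0L)
  active <- active[order(-obs[active], ord_keys[active])]
  cons <- list()                         # consensus vectors
  rel_to <- function(a) {
    # for allele a, compare against every consensus: 1 compat, -1 conflict, 0 disjoint
    vapply(cons, function(cv) {
      both <- !is.na(a) & !is.na(cv)
      if (!any(both)) return(0L)
      if (any(a[both] != cv[both])) return(-1L)
      1L
    }, integer(1))
  }
  ungrouped <- integer(0)
  for (i in active) {
    a <- mat[i, ]
    if (!length(cons)) {
      cons[[1L]] <- a
      gid[i] <- 1L
      next
    }
    r <- rel_to(a)
    if (all(r == -1L)) {
      cons[[length(cons) + 1L]] <- a
      gid[i] <- length(cons)
    } else if (sum(r == 1L) == 1L) {
      g <- which(r == 1L)
      cv <- cons[[g]]
      fill <- is.na(cv) & !is.na(a)
      cv[fill] <- a[fill]
      cons[[g]] <- cv
      gid[i] <- g
    } else {
      # compatible with >= 2 consensuses, or disjoint from all
      gid[i] <- NA_integer_
      ungrouped <- c(ungrouped, i)
    }
  }
  # final sweep: re-test ungrouped members against the finished consensuses
  for (i in ungrouped) {
    a <- mat[i, ]
    r <- rel_to(a)
    if (all(r == -1L)) {
      cons[[length(cons) + 1L]] <- a
      gid[i] <- length(cons)
    } else if (sum(r == 1L) == 1L) {
      g <- which(r == 1L)
      cv <- cons[[g]]
      fill <- is.na(cv) & !is.na(a)
      cv[fill] <- a[fill]
      cons[[g]] <- cv
      gid[i] <- g
    }
  }
  list(gid = gid, consensus = cons)
}

#' Group the haploblock alleles of a half-sib family
#'
#' Partitions a set of haploblock alleles (the parent-derived slots of one
#' half-sib family) into groups of mutually non-conflicting alleles whose
#' consensuses are pairwise incompatible. Members compatible with more than
#' one group consensus, or sharing no observed marker with any group, remain
#' ungrouped; entirely missing alleles are reported separately. Groups are
#' built greedily, seeding with the allele carrying most observed markers,
#' then re-testing ungrouped alleles against the finished consensuses.
#'
#' @param alleles A list of equal-length character vectors (`NA` = missing),
#'   or a character matrix with one row per member.
#' @param ids Optional character vector of member labels used for deterministic
#'   tie-breaking (defaults to input order).
#'
#' @return A list with components `groups` (a list, each with integer
#'   `members` indices into the input and a `consensus` vector), `ungrouped`
#'   and `all_missing` (integer index vectors).
#' @examples
#' h <- list(c("1","0","1","1","0","0"), c("1","0","1",NA,NA,NA),
#'           c(NA,"0","1","1","0","0"), c("0","1","1","0",NA,NA))
#' length(group_alleles(h)$groups)
#' @export
group_alleles <- function(alleles, ids = NULL) {
  mat <- if (is.matrix(alleles)) alleles else do.call(rbind, alleles)
  keys <- if (is.null(ids)) sprintf("%06d", seq_len(nrow(mat)))
          else as.character(ids)
  g <- .group_rows(mat, keys)
  grouped <- which(!is.na(g$gid) & g$gid > 0L)
  groups <- lapply(seq_along(g$consensus), function(k)
    list(members = grouped[g$gid[grouped] == k], consensus = g$consensus[[k]]))
  groups <- groups[vapply(groups, function(x) length(x$members) > 0L, logical(1))]
  list(groups = groups,
       ungrouped = which(is.na(g$gid)),
       all_missing = which(!is.na(g$gid) & g$gid == 0L))
}

#' Reject low-frequency markers
#'
#' For each marker, counts the occurrences of each observed allele symbol over
#' all haplotypes (two per individual). A polymorphic marker (two or more
#' distinct symbols observed) is rejected when any observed symbol occurs
#' fewer than `min_allele_count` times; a marker with no observations at all
#' is rejected with count 0. Monomorphic markers are retained: they cannot
#' create conflicts.
#'
#' @param haplo Character matrix of phased marker calls, two rows per
#'   individual (maternal then paternal haplotype), one column per marker;
#'   `NA` = missing.
#' @param min_allele_count Frequency threshold (default 3).
#'
#' @return A list with `retained` (character vector of marker names),
#'   `rejected` (character vector) and `diagnostics` (data.frame of
#'   `MARKER_FILTERED` records with the observed counts).
#' @export
filter_markers <- function(haplo, min_allele_count = 3) {
  markers <- colnames(haplo)
  if (is.null(markers)) stop("haplo must have marker column names", call. = FALSE)
  keep <- logical(length(markers))
  det <- character(length(markers))
  for (k in seq_along(markers)) {
    tab <- table(haplo[, k], useNA = "no")
    if (length(tab) == 0L) {
      keep[k] <- FALSE
      det[k] <- "no observations (count 0)"
    } else if (length(tab) == 1L) {
      keep[k] <- TRUE
    } else if (any(tab < min_allele_count)) {
      keep[k] <- FALSE
      det[k] <- paste0("allele counts ",
                       paste(names(tab), as.integer(tab), sep = ":", collapse = ","),
                       " below minimum ", min_allele_count)
    } else {
      keep[k] <- TRUE
    }
  }
  diag <- if (any(!keep)) data.frame(
    block_id = NA_character_,
    subject = markers[!keep],
    event = "MARKER_FILTERED",
    detail = det[!keep],
    stringsAsFactors = FALSE
  ) else .empty_diag()
  list(retained = markers[keep], rejected = markers[!keep], diagnostics = diag)
}

.empty_diag_df <- local({
  d <- data.frame(block_id = character(0), subject = character(0),
                  event = character(0), detail = character(0),
                  stringsAsFactors = FALSE)
  d
})
.empty_diag <- function() .empty_diag_df

#' Number the haploblock alleles occurring in a block
#'
#' Every distinct sequence of marker allele codes (including sequences with
#' missing values) that occurs in the pedigree is assigned its own haploblock
#' allele number. Numbers are dense from 1, in order of first appearance
#' scanning the haplotype rows top to bottom (individuals in pedigree order,
#' maternal before paternal haplotype). An entirely missing sequence gets the
#' reserved missing code `NA` rather than a number.
#'
#' @param haplo Character matrix: two rows per individual, one column per
#'   marker of the block.
#'
#' @return A list with `assignment` (integer vector, one entry per row of
#'   `haplo`; `NA` for all-missing rows) and `composition` (data.frame with
#'   column `allele` and one column per marker giving the allele's codes,
#'   `NA` = missing).
#' @export
catalog_alleles <- function(haplo) {
  n <- nrow(haplo)
  keys <- apply(haplo, 1L, function(r) paste(ifelse(is.na(r), "\x02", r), collapse = "\x01"))
  allmiss <- rowSums(!is.na(haplo)) == 0L
  assignment <- rep(NA_integer_, n)
  seen <- character(0)
  for (i in seq_len(n)) {
    if (allmiss[i]) next
    j <- match(keys[i], seen)
    if (is.na(j)) {
      seen <- c(seen, keys[i])
      j <- length(seen)
    }
    assignment[i] <- j
  }
  if (length(seen)) {
    first_rows <- match(seen, keys)
    comp <- as.data.frame(haplo[first_rows, , drop = FALSE],
                          stringsAsFactors = FALSE)
    rownames(comp) <- NULL
    comp <- cbind(data.frame(allele = seq_along(seen)), comp)
  } else {
    comp <- cbind(data.frame(allele = integer(0)),
                  as.data.frame(haplo[0, , drop = FALSE]))
  }
  list(assignment = assignment, composition = comp)
}

#' Name a haploblock allele
#'
#' Returns the allele number as a string, optionally suffixed with `_m<k>`
#' where `k` is the number of markers with missing values in the allele, to
#' flag alleles that differ from others only in missing data.
#'
#' @param number Integer allele number.
#' @param allele Character vector of the allele's marker codes (`NA` missing).
#' @param include_missing_count Append the `_m<k>` suffix when `k > 0`.
#' @return A character string.
#' @examples
#' allele_name(5, c("A", NA, NA), include_missing_count = TRUE)
#' @export
allele_name <- function(number, allele, include_missing_count = FALSE) {
  k <- sum(is.na(allele))
  if (include_missing_count && k > 0L) paste0(number, "_m", k)
  else as.character(number)
}
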