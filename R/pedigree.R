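#' Validate and topologically order a pedigree
#'
#' Checks a pedigree table (columns `id`, `mother`, `father`; `NA` for an
#' unknown parent) and returns it reordered so that every parent precedes all
#' of its offspring, founders (both parents unknown) first. Within these
#' constraints the original row order is preserved.
#'
#' @param pedigree A data.frame with character columns `id`, `mother`,
#'   `father`. Unknown parents are `NA` (readers also accept `"0"` or an empty
#'   field and normalise them to `NA`).
#'
#' @return The pedigree data.frame in topological order, with row names reset.
#' @seealso [hs_families()]
#' @examples
#' ped <- data.frame(id = c("C", "A", "B"),
#'                   mother = c("A", NA, NA),
#'                   father = c("B", NA, NA))
#' validate_pedigree(ped)$id
#' @export
validate_pedigree <- function(pedigree) {
  if (!is.data.frame(pedigree) || !all(c("id", "mother", "father") %in% names(pedigree)))
    stop("pedigree must be a data.frame with columns id, mother, father", call. = FALSE)
  ped <- data.frame(id = as.character(pedigree$id),
                    mother = as.character(pedigree$mother),
                    father = as.character(pedigree$father),
                    stringsAsFactors = FALSE)
  ped$mother[ped$mother %in% c("0", "", "NA")] <- NA_character_
  ped$father[ped$father %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(ped$id))
    stop("duplicated individual id in pedigree: ",
         ped$id[duplicated(ped$id)][1L], call. = FALSE)
  known <- c(ped$mother, ped$father)
  known <- unique(known[!is.na(known)])
  undeclared <- setdiff(known, ped$id)
  if (length(undeclared))
    stop("parent not declared as an individual: ", undeclared[1L], call. = FALSE)
  n <- nrow(ped)
  if (n == 0L) return(ped)

  # Kahn's algorithm; stable with respect to input order.
  idx <- seq_len(n)
  names(idx) <- ped$id
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$mother[i], ped$father[i])) {
      if (!is.na(p)) {
        pi <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[pi]] <- c(children[[pi]], i)
      }
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(order_out) < n) {
    on_cycle <- setdiff(seq_len(n), order_out)
    stop("pedigree contains a cycle involving individual: ",
         ped$id[on_cycle[1L]], call. = FALSE)
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a pedigree into half-sib families
#'
#' A half-sib (HS) family is one parent together with all (individual, slot)
#' pairs that inherited a gamete from it: the maternal slot of every
#' individual whose mother it is, and the paternal slot of every individual
#' whose father it is. Under self-fertilization one offspring contributes two
#' members (one per slot). Families are ordered by decreasing member count,
#' ties broken by ascending parent id.
#'
#' @param pedigree A validated pedigree (see [validate_pedigree()]).
#'
#' @return A list of families. Each family is a list with elements
#'   `parent_id`, `members` (data.frame `individual`, `slot` with slot values
#'   `"M"`/`"P"`) and `size`.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("A", "B", "E", "C", "D", "F"),
#'   mother = c(NA, NA, NA, "A", "A", "A"),
#'   father = c(NA, NA, NA, "B", "B", "E")))
#' sapply(hs_families(ped), `[[`, "size")
#' @export
hs_families <- function(pedigree) {
  ped <- pedigree
  fams <- list()
  add <- function(parent, individual, slot) {
    f <- fams[[parent]]
    if (is.null(f)) f <- list(individual = character(0), slot = character(0))
    f$individual <- c(f$individual, individual)
    f$slot <- c(f$slot, slot)
    fams[[parent]] <<- f
  }
  for (i in seq_len(nrow(ped))) {
    if (!is.na(ped$mother[i])) add(ped$mother[i], ped$id[i], "M")
    if (!is.na(ped$father[i])) add(ped$father[i], ped$id[i], "P")
  }
  if (!length(fams)) return(list())
  out <- lapply(names(fams), function(p) {
    m <- data.frame(individual = fams[[p]]$individual,
                    slot = fams[[p]]$slot,
                    stringsAsFactors = FALSE)
    list(parent_id = p, members = m, size = nrow(m))
  })
  sizes <- vapply(out, `[[`, integer(1), "size")
  parents <- vapply(out, `[[`, character(1), "parent_id")
  out[order(-sizes, parents)]
}

#' Half-sib family descriptors for the haplotype-matrix layout
#'
#' Translates [hs_families()] into row indices of the standard haplotype
#' matrix layout (two rows per individual in pedigree order: maternal then
#' paternal haplotype), the form consumed by [resolve_family()] and
#' [assign_block()].
#'
#' @param pedigree A validated pedigree.
#' @param block_id Optional block id attached to each descriptor (used in
#'   diagnostics).
#' @return A list of descriptors with elements `parent_rows`, `member_rows`,
#'   `member_labels`, `member_keys` and `parent_id`, ordered by decreasing
#'   family size.
#' @export
family_descriptors <- function(pedigree, block_id = NULL) {
  ids <- pedigree$id
  lapply(hs_families(pedigree), function(f) {
    pi <- match(f$parent_id, ids)
    list(parent_rows = c(2L * pi - 1L, 2L * pi),
         member_rows = 2L * match(f$members$individual, ids) -
           (f$members$slot == "M"),
         member_labels = paste0(f$members$individual, "|", f$members$slot),
         member_keys = paste0(f$members$individual, "\x01",
                              ifelse(f$members$slot == "M", "0", "1")),
         parent_id = f$parent_id,
         block_id = block_id)
  })
}
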