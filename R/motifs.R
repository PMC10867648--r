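#' The nine multichain circuit topology motif classes
#'
#' Two binary contacts (four distinct sites) on up to four chains realise
#' exactly nine topological relations: the single-chain series, parallel
#' and cross motifs (`S`, `P`, `X`); the two-chain independent, loop and
#' tandem motifs (`I2`, `L2`, `T2`); the three-chain independent and tandem
#' motifs (`I3`, `T3`); and the four-chain independent motif (`I4`).
#'
#' @format Character vector of the nine class labels.
#' @export
motif_classes <- c("S", "P", "X", "I2", "L2", "T2", "I3", "T3", "I4")

#' Classify the mutual relation of two contacts
#'
#' Implements the full decision tree over the chain memberships of the four
#' contact sites.  Writing a contact as its two sites, the tree first asks
#' whether contact A is intrachain: if so, the pair is one of the loop-
#' containing motifs (`S`/`P`/`X` when B shares the chain, `I2` when B is an
#' intrachain loop elsewhere, `T2`/`I3` when B is interchain); the
#' single-chain class is read off the site arrangement along the backbone
#' (`AABB` series, `ABBA` parallel, `ABAB` cross).  When both contacts are
#' interchain the pair is `L2` (both chains shared), `T3` (exactly one
#' chain shared) or `I4` (no chain shared).  Classification is symmetric
#' under renaming the contacts.
#'
#' Degenerate subtypes are reported for the two two-chain classes: an `L2`
#' loop is `parallel` when the two contacts occur in the same order along
#' both chains and `cross` otherwise; a `T2` tandem is `umbrella` when the
#' interchain contact attaches inside the loop and `arc` otherwise.
#'
#' @param c1,c2 contacts: one-row data.frames or vectors with
#'   `chain1, bead1, chain2, bead2`.
#' @return list with `label` (one of [motif_classes]) and `subtype`
#'   (`NA` except for `L2` and `T2`).
#' @examples
#' classify_pair(c(1, 1, 1, 5), c(1, 3, 2, 4))  # T2 umbrella
#' @export
classify_pair <- function(c1, c2) {
  s <- .pair_sites(c1, c2)
  A <- s$A; B <- s$B
  a_intra <- A$chain[1] == A$chain[2]
  b_intra <- B$chain[1] == B$chain[2]
  if (a_intra && b_intra) {
    if (A$chain[1] == B$chain[1]) {
      ord <- order(c(A$bead, B$bead))
      pat <- paste(c("A", "A", "B", "B")[ord], collapse = "")
      lab <- switch(pat, AABB = "S", BBAA = "S", ABBA = "P", BAAB = "P",
                    ABAB = "X", BABA = "X")
      return(list(label = lab, subtype = NA_character_))
    }
    return(list(label = "I2", subtype = NA_character_))
  }
  if (xor(a_intra, b_intra)) {
    intra <- if (a_intra) A else B
    inter <- if (a_intra) B else A
    p1 <- intra$chain[1]
    hit <- which(inter$chain == p1)
    if (length(hit)) {
      # three sites on one chain: tandem; inside the loop = umbrella
      sb <- inter$bead[hit[1]]
      sub <- if (sb > min(intra$bead) && sb < max(intra$bead)) "umbrella" else "arc"
      return(list(label = "T2", subtype = sub))
    }
    return(list(label = "I3", subtype = NA_character_))
  }
  shared <- intersect(A$chain, B$chain)
  if (length(shared) == 0L) return(list(label = "I4", subtype = NA_character_))
  if (length(shared) == 1L) return(list(label = "T3", subtype = NA_character_))
  # both chains shared: loop; orientation along the two chains gives subtype
  u <- shared[1]; v <- shared[2]
  au <- A$bead[A$chain == u]; bu <- B$bead[B$chain == u]
  av <- A$bead[A$chain == v]; bv <- B$bead[B$chain == v]
  sub <- if (sign(au - bu) == sign(av - bv)) "parallel" else "cross"
  list(label = "L2", subtype = sub)
}

.pair_sites <- function(c1, c2) {
  cv <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[1, c("chain1", "bead1", "chain2", "bead2")])
    x <- as.integer(x[1:4])
    list(chain = x[c(1, 3)], bead = x[c(2, 4)])
  }
  A <- cv(c1); B <- cv(c2)
  sites <- rbind(cbind(A$chain, A$bead), cbind(B$chain, B$bead))
  if (anyDuplicated(paste(sites[, 1], sites[, 2])))
    stop("contacts share a site; the motif alphabet requires 4 distinct sites")
  list(A = A, B = B)
}

#' Ghost-contact string notation of a contact pair
#'
#' Builds the string over `{A, B, O}` describing the arrangement of the two
#' contacts on their chains.  Participating chains are placed side by side
#' in order of appearance; each chain contributes its contact sites in
#' backbone order, padded at the bottom with ghost contacts `O` to a common
#' height; the string is read level by level (top to bottom), left to right
#' within a level.
#'
#' @inheritParams classify_pair
#' @return list with `text` (the string), `n_chains`, and the per-chain
#'   site matrix as attribute-free `columns`.
#' @examples
#' string_notation(c(1, 1, 1, 5), c(1, 3, 2, 4))$text  # "ABBOAO"
#' @export
string_notation <- function(c1, c2) {
  s <- .pair_sites(c1, c2)
  sites <- data.frame(chain = c(s$A$chain, s$B$chain),
                      bead = c(s$A$bead, s$B$bead),
                      lab = c("A", "A", "B", "B"))
  chains <- unique(sites$chain)
  cols <- lapply(chains, function(ch) {
    sub <- sites[sites$chain == ch, , drop = FALSE]
    sub$lab[order(sub$bead)]
  })
  h <- max(lengths(cols))
  cols <- lapply(cols, function(cl) c(cl, rep("O", h - length(cl))))
  text <- paste(unlist(lapply(seq_len(h), function(lv)
    vapply(cols, `[`, character(1), lv))), collapse = "")
  list(text = text, n_chains = length(chains), columns = cols)
}

#' Circuit topology motif fractions of a conformation
#'
#' Detects contacts, classifies every unordered pair of contacts that does
#' not share a site, and reports the fraction of pairs in each of the nine
#' motif classes (degenerate subtypes aggregated).  With fewer than two
#' contacts there are no pairs: the fractions are returned as `NA` and the
#' row is flagged via `n_pairs = 0` rather than raising an error.
#'
#' @param system a [chain_system()].
#' @param config a [contact_config()].
#' @param contacts optional precomputed contact table (skips detection).
#' @return One-row `data.frame` with the nine class fractions, `n_contacts`,
#'   `n_pairs` and `n_pairs_skipped` (pairs sharing a site).
#' @examples
#' sys <- chain_system(lapply(0:3, function(k) cbind(c(0, 1), 1.1 * k, 0)))
#' motif_fractions(sys)
#' @export
motif_fractions <- function(system, config = contact_config(), contacts = NULL) {
  if (is.null(contacts)) contacts <- detect_contacts(system, config)
  nc <- nrow(contacts)
  counts <- stats::setNames(numeric(length(motif_classes)), motif_classes)
  skipped <- 0L
  if (nc >= 2L) {
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      r <- tryCatch(classify_pair(contacts[i, ], contacts[j, ]),
                    error = function(e) NULL)
      if (is.null(r)) skipped <- skipped + 1L
      else counts[r$label] <- counts[r$label] + 1
    }
  }
  npairs <- sum(counts)
  fr <- if (npairs > 0) counts / npairs else rep(NA_real_, length(counts))
  out <- as.data.frame(as.list(fr))
  names(out) <- motif_classes
  out$n_contacts <- nc
  out$n_pairs <- npairs
  out$n_pairs_skipped <- skipped
  out
}
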