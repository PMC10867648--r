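#' Contact detection configuration
#'
#' Two beads form a contact when their Euclidean distance (minimum-image if
#' the system is periodic) does not exceed the cutoff `rc` (default 1.4
#' sigma).  Pairs on the same chain additionally require a backbone index
#' separation of at least `min_backbone_sep` (default 3), so that bonded
#' and next-nearest neighbours never count as contacts and no two-bond
#' loops arise.  Alternatively, `rc_intra` replaces the distance cutoff for
#' intrachain pairs when the self-interaction range should differ from the
#' interchain one.
#'
#' @param rc contact cutoff distance in sigma units.
#' @param min_backbone_sep minimal intrachain index separation (>= 1).
#' @param rc_intra optional separate Euclidean cutoff for intrachain pairs.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(rc = 1.4, min_backbone_sep = 3L, rc_intra = NULL) {
  if (rc <= 0) stop("rc must be positive")
  if (min_backbone_sep < 1L) stop("min_backbone_sep must be >= 1")
  structure(list(rc = rc, min_backbone_sep = as.integer(min_backbone_sep),
                 rc_intra = rc_intra),
            class = "contact_config")
}

#' Detect binary contacts on a multichain conformation
#'
#' Scans all unordered bead pairs and returns those within the cutoff,
#' excluding intrachain pairs closer than `min_backbone_sep` along the
#' backbone.  Ordering is deterministic: lexicographic in
#' (chain1, bead1, chain2, bead2) with the smaller site first.
#'
#' @param system a [chain_system()].
#' @param config a [contact_config()].
#' @return A `data.frame` with integer columns `chain1`, `bead1`, `chain2`,
#'   `bead2` and numeric `dist`, one row per contact.
#' @examples
#' sys <- chain_system(list(cbind(c(0, 1), 0, 0), cbind(c(0, 1), 1.2, 0)))
#' detect_contacts(sys, contact_config())
#' @export
detect_contacts <- function(system, config = contact_config()) {
  fl <- .flatten(system)
  xyz <- fl$xyz
  nb <- nrow(xyz)
  d2 <- .pair_dist2(xyz, system$box)
  rc2 <- config$rc^2
  rci2 <- if (is.null(config$rc_intra)) rc2 else config$rc_intra^2
  idx <- which(upper.tri(d2), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- fl$chain[i] == fl$chain[j]
  keep <- (!same & d2[idx] <= rc2) |
    (same & d2[idx] <= rci2 & abs(fl$bead[i] - fl$bead[j]) >= config$min_backbone_sep)
  i <- i[keep]; j <- j[keep]
  res <- data.frame(chain1 = fl$chain[i], bead1 = fl$bead[i],
                    chain2 = fl$chain[j], bead2 = fl$bead[j],
                    dist = sqrt(d2[cbind(i, j)]))
  # canonical site order within each contact, then lexicographic rows
  flip <- res$chain1 > res$chain2 |
    (res$chain1 == res$chain2 & res$bead1 > res$bead2)
  tmp <- res[flip, c("chain2", "bead2", "chain1", "bead1")]
  res[flip, c("chain1", "bead1", "chain2", "bead2")] <- tmp
  res <- res[order(res$chain1, res$bead1, res$chain2, res$bead2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# squared pairwise distances, minimum image when box present
.pair_dist2 <- function(xyz, box) {
  n <- nrow(xyz)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  d2
}
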