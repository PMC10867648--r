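#' Equilibrate a system by sliding-window stationarity
#'
#' Runs the thermostatted dynamics in blocks of `block_tau` and stops when
#' the block means of the normalized radius of gyration and of the
#' end-to-end correlation parameter both change by less than `tol`
#' between consecutive blocks (after a minimum of `min_blocks`), or when
#' `max_tau` is reached.
#'
#' @param config a [sim_config()]; its `steps`/`stride` are overridden per
#'   block.
#' @param system optional starting [chain_system()].
#' @param block_tau block length in tau.
#' @param max_tau hard cap on total simulated time.
#' @param tol stationarity tolerance on the block means.
#' @param min_blocks minimum number of blocks before testing.
#' @return list with `system` (final conformation), `velocities`, `history`
#'   (per-block observable means) and `time` (tau simulated).
#' @export
equilibrate <- function(config, system = NULL, block_tau = 100,
                        max_tau = 2000, tol = 0.05, min_blocks = 3L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(system)) system <- init_system_noseed(config)
  cfg <- config
  cfg$seed <- NULL
  cfg$steps <- as.integer(round(block_tau / config$dt))
  cfg$stride <- max(1L, cfg$steps %/% 10L)
  vel <- NULL
  hist <- NULL
  t_done <- 0
  prev <- NULL
  repeat {
    tr <- run_nvt(system, cfg, velocities = vel)
    system <- tr$frames[[length(tr$frames)]]
    vel <- tr$final$v
    obs <- do.call(rbind, lapply(tr$frames, observables_record))
    cur <- colMeans(obs[, c("Rg_tilde", "CR")])
    t_done <- t_done + block_tau
    hist <- rbind(hist, data.frame(time = t_done, Rg_tilde = cur[1], CR = cur[2]))
    if (!is.null(prev) && nrow(hist) >= min_blocks &&
        abs(cur[1] - prev[1]) < tol * max(abs(prev[1]), 0.1) &&
        abs(cur[2] - prev[2]) < tol) break
    if (t_done >= max_tau) break
    prev <- cur
  }
  list(system = system, velocities = vel, history = hist, time = t_done)
}

#' Stiffness sweep: simulate, analyze topology, aggregate
#'
#' For every bending stiffness in `kappas` and every replica: equilibrate
#' a fresh system by the stationarity criterion, then record the
#' structural observables, circuit topology motif fractions, and -- after
#' primitive path analysis and braid extraction -- the four braid
#' measures.  Replica seeds derive deterministically from `seed`, so the
#' sweep is reproducible from the seed alone.
#'
#' The defaults are a desk-scale profile (four chains of ten beads at unit
#' temperature and density 0.01); ensemble sizes and equilibration lengths
#' scale with the arguments.
#'
#' @param kappas bending stiffness grid.
#' @param replicas independent realizations per stiffness.
#' @param config base [sim_config()] (kappa and seed are overridden).
#' @param seed master seed.
#' @param block_tau,max_tau,tol equilibration controls, see
#'   [equilibrate()].
#' @param log_base complexity logarithm base.
#' @param contact_cfg a [contact_config()].
#' @param ppa_analysis run primitive path analysis + braid extraction
#'   (default TRUE).
#' @return list of class `ct_sweep`: `results` (one row per replica) and
#'   `summary` (per-kappa means and standard deviations).
#' @examples
#' \donttest{
#' sw <- run_sweep(kappas = c(0, 12), replicas = 2, seed = 1,
#'                 block_tau = 20, max_tau = 60)
#' }
#' @export
run_sweep <- function(kappas = seq(0, 12, by = 2), replicas = 20L,
                      config = sim_config(), seed = 1L,
                      block_tau = 100, max_tau = 2000, tol = 0.05,
                      log_base = 3, contact_cfg = contact_config(),
                      ppa_analysis = TRUE) {
  rows <- list()
  for (ki in seq_along(kappas)) {
    for (r in seq_len(replicas)) {
      cfg <- config
      cfg$kappa <- kappas[ki]
      cfg$seed <- as.integer((seed * 10007L + ki * 211L + r) %% .Machine$integer.max)
      row <- tryCatch(
        .sweep_one(cfg, block_tau, max_tau, tol, log_base, contact_cfg,
                   ppa_analysis),
        error = function(e) NULL)
      if (is.null(row)) {
        rows[[length(rows) + 1L]] <- data.frame(kappa = cfg$kappa,
                                                replica = r, failed = TRUE)
        next
      }
      row$kappa <- cfg$kappa
      row$replica <- r
      row$failed <- FALSE
      row$seed <- cfg$seed
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(.sweep_cols, names(r))
    for (m in miss) r[[m]] <- NA
    r[.sweep_cols]
  }))
  ok <- results[!results$failed, , drop = FALSE]
  numcols <- setdiff(.sweep_cols, c("kappa", "replica", "failed", "seed",
                                    "tn_class", "reduced_word"))
  if (nrow(ok)) {
    agg <- function(f) stats::aggregate(ok[, numcols],
                                        by = list(kappa = ok$kappa),
                                        FUN = f, na.rm = TRUE)
    summary <- list(mean = agg(function(x, na.rm) mean(x, na.rm = na.rm)),
                    sd = agg(function(x, na.rm) stats::sd(x, na.rm = na.rm)))
  } else {
    warning("all sweep replicas failed")
    empty <- ok[, c("kappa", numcols)]
    summary <- list(mean = empty, sd = empty)
  }
  structure(list(results = results, summary = summary,
                 kappas = kappas, replicas = replicas, seed = seed),
            class = "ct_sweep")
}

.sweep_cols <- c("kappa", "replica", "failed", "seed", "Rg", "Rg_tilde", "CR",
                 "bond_length", "S", "P", "X", "I2", "L2", "T2", "I3", "T3",
                 "I4", "inter_sum", "n_contacts", "n_pairs",
                 "writhe", "minimal_length", "complexity", "CL_ratio",
                 "tn_class", "reduced_word")

.sweep_one <- function(cfg, block_tau, max_tau, tol, log_base, contact_cfg,
                       ppa_analysis) {
  eq <- equilibrate(cfg, block_tau = block_tau, max_tau = max_tau, tol = tol)
  sys <- eq$system
  obs <- observables_record(sys)
  mf <- motif_fractions(sys, contact_cfg)
  row <- data.frame(obs, bond_length = mean_bond_length(sys),
                    mf[motif_classes], n_contacts = mf$n_contacts,
                    n_pairs = mf$n_pairs)
  row$inter_sum <- with(row, L2 + T3 + I4)
  if (ppa_analysis) {
    pp <- suppressWarnings(primitive_paths(sys, cfg))
    word <- extract_braid(pp)
    inv <- braid_invariants(word, log_base = log_base)
    row$writhe <- inv$writhe
    row$minimal_length <- inv$minimal_length
    row$complexity <- inv$complexity
    row$CL_ratio <- if (inv$minimal_length > 0)
      inv$complexity / inv$minimal_length else NA_real_
    row$tn_class <- inv$tn_class
    row$reduced_word <- inv$reduced_word
  }
  row
}

#' @export
print.ct_sweep <- function(x, ...) {
  cat("<ct_sweep>", length(x$kappas), "stiffness values x", x$replicas,
      "replicas (seed", x$seed, ")\n")
  print(x$summary$mean[, c("kappa", "Rg_tilde", "CR", "inter_sum",
                           "minimal_length", "complexity")])
  invisible(x)
}

#' Combined contact / braid string serialization
#'
#' Interleaves the ghost-contact tuples of the detected contacts with the
#' braid generators of the extracted word, ordered by height along the
#' braid axis.  Contacts are labelled `A`, `B`, `C`, ... in height order;
#' each contributes one tuple of per-position characters (`O` marks a
#' position without a site at that level); generators appear as signed
#' integers.  The representation is a serialization format only; braid and
#' motif computations use the dedicated routines.
#'
#' @param system a [chain_system()].
#' @param contacts optional precomputed contact table.
#' @param frame optional [find_projection_frame()] result.
#' @param config a [contact_config()].
#' @return Character scalar of whitespace-separated tokens; alphabetic
#'   tokens are contact tuples, numeric tokens are braid generators.
#' @examples
#' parse_braided_string("AOA -2 -1 2 BBO 2")
#' @export
braided_string <- function(system, contacts = NULL, frame = NULL,
                           config = contact_config()) {
  M <- n_chains(system)
  if (is.null(contacts)) contacts <- detect_contacts(system, config)
  if (M < 2) stop("need at least two chains")
  if (is.null(frame)) frame <- find_projection_frame(system)
  ev <- .extract_events(system, frame)
  sys <- unwrap_system(system)
  zb <- function(c, b) {
    p <- sys$chains[[c]][b, ]
    sum((p - frame$origin) * frame$axes[, 3])
  }
  tokens <- list()
  if (nrow(contacts) > 26L)
    stop("combined string serialization supports at most 26 contacts")
  if (nrow(contacts)) {
    zc <- vapply(seq_len(nrow(contacts)), function(i)
      (zb(contacts$chain1[i], contacts$bead1[i]) +
       zb(contacts$chain2[i], contacts$bead2[i])) / 2, numeric(1))
    labs <- LETTERS[seq_len(nrow(contacts))][order(order(zc))]
    for (i in seq_len(nrow(contacts))) {
      poschain <- ev$order_at(zc[i])
      tup <- rep("O", M)
      tup[match(contacts$chain1[i], poschain)] <- labs[i]
      tup[match(contacts$chain2[i], poschain)] <- labs[i]
      tokens[[length(tokens) + 1L]] <- list(z = zc[i],
                                            tok = paste(tup, collapse = ""))
    }
  }
  if (length(ev$letters))
    for (k in seq_along(ev$letters))
      tokens[[length(tokens) + 1L]] <- list(z = ev$z[k],
                                            tok = as.character(ev$letters[k]))
  if (!length(tokens)) return("")
  zs <- vapply(tokens, `[[`, numeric(1), "z")
  paste(vapply(tokens[order(zs)], `[[`, character(1), "tok"), collapse = " ")
}

#' @rdname braided_string
#' @param text a serialized combined string.
#' @return `parse_braided_string()` returns a list with `tuples`
#'   (character vector) and `letters` (integer generator sequence).
#' @export
parse_braided_string <- function(text) {
  if (!nzchar(trimws(text))) return(list(tuples = character(0),
                                         letters = integer(0)))
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  is_gen <- grepl("^-?[0-9]+$", tok)
  list(tuples = tok[!is_gen], letters = as.integer(tok[is_gen]))
}

# crossing events with heights, plus a lookup for the strand order at a
# given height; shared by extract_braid and braided_string
.extract_events <- function(system, frame, n_slices = NULL) {
  M <- n_chains(system)
  if (is.null(n_slices)) n_slices <- 10L * nrow(system$chains[[1]])
  sys <- unwrap_system(system)
  loc <- lapply(seq_len(M), function(c) {
    ch <- sweep(sys$chains[[c]], 2, frame$origin) %*% frame$axes
    if (frame$plane_of_chain[c] < 0) ch <- ch[nrow(ch):1, , drop = FALSE]
    ch
  })
  zlev <- seq(0, frame$offset, length.out = n_slices + 1L)
  backtrack <- numeric(M)
  xy <- lapply(seq_len(M), function(c) {
    ch <- loc[[c]]
    z <- ch[, 3]
    backtrack[c] <<- sum(pmax(0, -diff(z))) / max(sum(abs(diff(z))), 1e-12)
    zm <- cummax(z) + seq_along(z) * 1e-12
    cbind(stats::approx(zm, ch[, 1], xout = zlev, rule = 2)$y,
          stats::approx(zm, ch[, 2], xout = zlev, rule = 2)$y)
  })
  X <- vapply(xy, function(m) m[, 1], numeric(n_slices + 1L))
  Y <- vapply(xy, function(m) m[, 2], numeric(n_slices + 1L))
  X <- X + outer(rep(1e-9, n_slices + 1L), seq_len(M))
  letters <- integer(0)
  zev <- numeric(0)
  for (k in seq_len(n_slices)) {
    x0 <- X[k, ]; x1 <- X[k + 1L, ]
    tbase <- 0
    repeat {
      pos <- order(x0)
      tcross <- rep(Inf, M - 1L)
      for (q in seq_len(M - 1L)) {
        sL <- pos[q]; sR <- pos[q + 1L]
        d0 <- x0[sR] - x0[sL]
        d1 <- x1[sR] - x1[sL]
        if (d0 > 0 && d1 < 0) tcross[q] <- d0 / (d0 - d1)
      }
      if (all(!is.finite(tcross))) break
      q <- which.min(tcross)
      tq <- tcross[q]
      sL <- pos[q]; sR <- pos[q + 1L]
      yL <- Y[k, sL] + tq * (Y[k + 1L, sL] - Y[k, sL])
      yR <- Y[k, sR] + tq * (Y[k + 1L, sR] - Y[k, sR])
      letters <- c(letters, if (yL > yR) q else -q)
      zev <- c(zev, zlev[k] + (tbase + (1 - tbase) * tq) * (zlev[k + 1L] - zlev[k]))
      x0 <- (x0 + tq * (x1 - x0)) + 1e-9 * (x1 - x0)
      tbase <- tbase + (1 - tbase) * tq
    }
  }
  order_at <- function(z) {
    k <- which.min(abs(zlev - z))
    order(X[k, ])
  }
  list(letters = letters, z = zev, backtrack = backtrack,
       order_at = order_at, X = X, Y = Y, zlev = zlev,
       strand_order = order(X[1, ]))
}
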