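# Synthetic flowering-record communities with controllable life-form
# structure (onset synchrony, duration mean/variance), plus Yule trees and
# Brownian-motion traits for the phylogenetic-signal machinery. The
# generator reproduces the weekly observation protocol: true flowering
# intervals are continuous, but only their intersection with the census
# calendar is recorded.

#' Per-life-form simulation parameters
#'
#' Controls the community structure generated for one life form. Onsets are
#' hierarchical: a species' peak onset is normal around
#' `peak_onset_mean` (between-species spread `peak_onset_sd_between`), and
#' individual onsets are normal around the species peak with spread
#' `onset_sd_within` -- the intraspecific synchrony dial (small for
#' mass-flowering trees, large for extended-flowering herbs). Individual
#' flowering lengths are gamma with species-level mean around `mfl_mean`
#' (spread `mfl_sd_between`) and within-species variance `vfl_within`,
#' truncated at 1 day.
#'
#' @param n_species number of species.
#' @param n_individuals_range integer `c(min, max)` individuals per species.
#' @param peak_onset_mean mean species peak onset, day of year.
#' @param peak_onset_sd_between between-species SD of peak onset (days).
#' @param onset_sd_within within-species SD of individual onsets (days).
#' @param mfl_mean mean of species mean flowering length (days, >= 1).
#' @param mfl_sd_between between-species SD of mean flowering length.
#' @param vfl_within within-species variance of flowering length (days^2).
#' @return a `life_form_params` list.
#' @export
life_form_params <- function(n_species, n_individuals_range = c(5L, 30L),
                             peak_onset_mean = 110, peak_onset_sd_between = 25,
                             onset_sd_within = 8, mfl_mean = 20,
                             mfl_sd_between = 4, vfl_within = 50) {
  stopifnot(n_species >= 1L, length(n_individuals_range) == 2L,
            n_individuals_range[1L] >= 1L,
            n_individuals_range[1L] <= n_individuals_range[2L],
            peak_onset_sd_between >= 0, onset_sd_within >= 0,
            mfl_mean >= 1, mfl_sd_between >= 0, vfl_within >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_individuals_range = as.integer(n_individuals_range),
                 peak_onset_mean = peak_onset_mean,
                 peak_onset_sd_between = peak_onset_sd_between,
                 onset_sd_within = onset_sd_within,
                 mfl_mean = mfl_mean, mfl_sd_between = mfl_sd_between,
                 vfl_within = vfl_within),
            class = "life_form_params")
}

#' Default community configuration
#'
#' A three-life-form community sized like a temperate-forest flowering
#' survey: 13 tree, 15 perennial and 20 annual species, weekly censuses
#' from 1 March to 31 July. Trees flower briefly and synchronously (small
#' within-species onset spread and length variance, peak in May); perennial
#' herbs and annuals flower longer and less synchronously, annuals starting
#' earliest. Mean flowering length is the same across life forms, so
#' differences in total flowering length arise from synchrony and length
#' variance alone.
#'
#' @return named list of [life_form_params()] (`tree`, `perennial`,
#'   `annual`).
#' @export
default_sim_config <- function() {
  list(
    tree = life_form_params(13L, c(5L, 30L), peak_onset_mean = 130,
                            peak_onset_sd_between = 25, onset_sd_within = 3,
                            mfl_mean = 20, mfl_sd_between = 4, vfl_within = 9),
    perennial = life_form_params(15L, c(5L, 30L), peak_onset_mean = 110,
                                 peak_onset_sd_between = 28, onset_sd_within = 12,
                                 mfl_mean = 20, mfl_sd_between = 4, vfl_within = 64),
    annual = life_form_params(20L, c(5L, 30L), peak_onset_mean = 95,
                              peak_onset_sd_between = 22, onset_sd_within = 14,
                              mfl_mean = 20, mfl_sd_between = 4, vfl_within = 100)
  )
}

#' Simulate a flowering-record dataset under the weekly census protocol
#'
#' Generates individual flowering intervals per the hierarchical model in
#' [life_form_params()] and records only what a weekly census would see:
#' observed onset (end) is the first (last) census date covered by the true
#' interval, and individuals whose interval covers no census date are
#' censored out entirely. Species parameters are drawn once and shared
#' across years (an optional additive year offset shifts all onsets in later
#' years). Genus labels are assigned round-robin over species ordered by
#' peak onset, with at most 3 species per genus, to give the random-intercept
#' models realistic shallow structure; families group two genera each.
#'
#' @param config named list of [life_form_params()] (names = life forms),
#'   e.g. [default_sim_config()].
#' @param calendars a [census_calendar()] or list of them (one per year).
#' @param seed integer seed (determinism contract: same config + seed gives
#'   an identical dataset).
#' @param year_offset additive shift (days) of all true onsets per year
#'   after the first, default 0.
#' @return list with `dataset` (a [pheno_dataset()]) and `manifest` (seed,
#'   per-species true parameters, record count).
#' @export
simulate_records <- function(config, calendars, seed = NULL, year_offset = 0) {
  if (inherits(calendars, "census_calendar")) calendars <- list(calendars)
  stopifnot(length(calendars) >= 1L,
            all(vapply(calendars, inherits, TRUE, "census_calendar")))
  if (is.null(names(config)) || !all(names(config) %in% LIFE_FORMS)) {
    stopf("config must be a named list with names among: %s",
          paste(LIFE_FORMS, collapse = ", "))
  }
  with_seed(seed, {
    # species-level true parameters, drawn once
    sp_rows <- list()
    for (lf in names(config)) {
      p <- config[[lf]]
      for (s in seq_len(p$n_species)) {
        sp_rows[[length(sp_rows) + 1L]] <- data.frame(
          species = sprintf("%s_sp%02d", lf, s),
          life_form = lf,
          peak_onset = stats::rnorm(1L, p$peak_onset_mean, p$peak_onset_sd_between),
          onset_sd = p$onset_sd_within,
          mfl = max(1, stats::rnorm(1L, p$mfl_mean, p$mfl_sd_between)),
          vfl = p$vfl_within,
          n_target = p$n_individuals_range[1L] +
            sample.int(p$n_individuals_range[2L] - p$n_individuals_range[1L] + 1L, 1L) - 1L,
          stringsAsFactors = FALSE)
      }
    }
    sp <- do.call(rbind, sp_rows)
    # genus assignment: round-robin over species ordered by peak onset,
    # <= 3 species per genus
    ord <- order(sp$peak_onset)
    n_gen <- ceiling(nrow(sp) / 3)
    gidx <- integer(nrow(sp))
    gidx[ord] <- rep_len(seq_len(n_gen), nrow(sp))
    sp$genus <- sprintf("G%02d", gidx)
    sp$family <- sprintf("F%02d", ceiling(gidx / 2))

    recs <- list()
    for (yi in seq_along(calendars)) {
      cal <- calendars[[yi]]
      doy <- as.numeric(cal$dates) - as.numeric(as.Date(sprintf("%d-01-01", cal$year))) + 1
      shift <- (yi - 1L) * year_offset
      for (i in seq_len(nrow(sp))) {
        onset_true <- stats::rnorm(sp$n_target[i], sp$peak_onset[i] + shift,
                                   sp$onset_sd[i])
        len_true <- if (sp$vfl[i] > 0) {
          stats::rgamma(sp$n_target[i], shape = sp$mfl[i]^2 / sp$vfl[i],
                        rate = sp$mfl[i] / sp$vfl[i])
        } else {
          rep(sp$mfl[i], sp$n_target[i])
        }
        len_true <- pmax(1, len_true)
        end_true <- onset_true + len_true
        obs <- lapply(seq_along(onset_true), function(k) {
          covered <- which(doy >= onset_true[k] & doy <= end_true[k])
          if (!length(covered)) return(NULL)  # censored: never seen in flower
          c(first = covered[1L], last = covered[length(covered)])
        })
        kept <- !vapply(obs, is.null, TRUE)
        if (!any(kept)) next
        ob <- do.call(rbind, obs[kept])
        recs[[length(recs) + 1L]] <- data.frame(
          species = sp$species[i], genus = sp$genus[i], family = sp$family[i],
          life_form = sp$life_form[i], year = cal$year,
          individual_id = sprintf("%s_y%d_i%02d", sp$species[i], cal$year,
                                  which(kept)),
          onset = cal$dates[ob[, "first"]], end = cal$dates[ob[, "last"]],
          stringsAsFactors = FALSE)
      }
    }
    if (!length(recs)) stopf("no individual covered any census date")
    records <- do.call(rbind, recs)
    rownames(records) <- NULL

    observed_sp <- unique(records$species)
    lost <- setdiff(sp$species, observed_sp)
    if (length(lost)) {
      warnf("species with zero observable individuals dropped: %s",
            paste(lost, collapse = ", "))
    }
    meta <- sp[sp$species %in% observed_sp,
               c("species", "genus", "family", "life_form")]
    rownames(meta) <- NULL
    ds <- pheno_dataset(records, calendars, meta)
    list(dataset = ds,
         manifest = list(seed = seed, species = sp, n_records = nrow(records)))
  })
}

#' Simulate a Yule (pure-birth) tree
#'
#' Constructs an ultrametric pure-birth tree by the standard waiting-time
#' recipe: starting from the root split (two lineages), the time spent with
#' `k` lineages is exponential with rate `k * birth_rate`, a uniformly
#' chosen lineage splits at each event, and a final exponential stretch with
#' all `n_tips` lineages alive ends the simulation. The expected root-to-tip
#' depth is \eqn{\sum_{k=2}^{n} 1 / (k \lambda)}.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate lambda (> 0), default 1.
#' @param seed integer seed or `NULL`.
#' @return an ultrametric `phylo` tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2L, birth_rate > 0)
  with_seed(seed, {
    n_nodes_total <- 2L * n_tips - 1L
    parent <- integer(n_nodes_total)   # 0 = root
    t_end <- numeric(n_nodes_total)    # time the node splits (or present)
    # internal ids as created: 1 = root (splits at time 0)
    parent[2:3] <- 1L
    alive <- c(2L, 3L)
    nxt <- 4L
    t <- 0
    k <- 2L
    while (k < n_tips) {
      t <- t + stats::rexp(1L, k * birth_rate)
      i <- alive[sample.int(k, 1L)]
      t_end[i] <- t
      parent[nxt] <- i; parent[nxt + 1L] <- i
      alive <- c(alive[alive != i], nxt, nxt + 1L)
      nxt <- nxt + 2L
      k <- k + 1L
    }
    t_end[alive] <- t + stats::rexp(1L, n_tips * birth_rate)

    # map to ape numbering: tips 1..n, root n+1, internals by split time
    is_tip <- seq_len(n_nodes_total) %in% alive
    internal <- which(!is_tip)
    internal <- internal[order(t_end[internal])]   # root (t=0) first
    map <- integer(n_nodes_total)
    map[alive] <- seq_len(n_tips)
    map[internal] <- n_tips + seq_along(internal)
    edge <- cbind(map[parent[-1L]], map[seq_len(n_nodes_total)[-1L]])
    t_start <- t_end[parent[-1L]]
    tree <- structure(list(edge = edge,
                           edge.length = t_end[-1L] - t_start,
                           tip.label = paste0("t", seq_len(n_tips)),
                           Nnode = n_tips - 1L),
                      class = "phylo", order = "cladewise")
    # tips were labelled by alive-order; rebuild labels in tip-number order
    tree$tip.label <- paste0("t", seq_len(n_tips))
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Root value 0; along each branch the trait accrues an independent normal
#' increment with variance `sigma2 *` branch length. Tip covariances
#' therefore equal `sigma2 *` shared path length from the root.
#'
#' @param tree a `phylo` tree.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param seed integer seed or `NULL`.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    tr <- stats::reorder(tree, "postorder")
    n_all <- ntip + tr$Nnode
    val <- numeric(n_all)
    inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
    # preorder = reversed postorder: parents are set before children
    for (e in rev(seq_len(nrow(tr$edge)))) {
      val[tr$edge[e, 2L]] <- val[tr$edge[e, 1L]] + inc[e]
    }
    out <- val[seq_len(ntip)]
    names(out) <- tr$tip.label
    out
  })
}
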