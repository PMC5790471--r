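# Synthetic paired-profile generator.
#
# Both branches of a pair start from a shared diploid-heterozygous genome,
# receive shared trunk events, then private branch events, then (optionally)
# a whole-genome doubling. Two modes:
#   * free mode (target_discordance = "free"): Poisson numbers of trunk and
#     branch events with log-uniform lengths and weighted types;
#   * targeted mode (numeric target_discordance): disjoint blocks are
#     allocated to event classes so that the window-level CN discordance,
#     metastasis-only LOH and primary-only LOH fractions of the emitted pair
#     hit planted budgets under the same +1/+2 correction semantics the
#     pipeline applies.
# Ground truth is recomputed from the emitted profiles by the independent
# interval-arithmetic engine in truth.R, never by the pipeline path.

#' Simulation configuration
#'
#' @param layout [genome_layout()] to simulate on. Default: 22 autosomes of
#'   5 Mb (11,000 windows of 10 kb).
#' @param window_size window size in bp used for budgets and ground truth.
#' @param trunk_event_rate expected shared (trunk) events per genome
#'   (free mode).
#' @param branch_event_rates expected private events per branch, named
#'   `primary` and `met` (free mode).
#' @param event_length min/max of the log-uniform event length draw, bp.
#' @param event_type_weights weights over loss, gain, amp, homdel, cn_loh
#'   (free mode; normalized to sum to 1).
#' @param target_discordance `"free"` or a planted window-level CN
#'   discordance fraction in \[0, 1\] (targeted mode).
#' @param loh_met_fraction,loh_primary_fraction planted metastasis-only /
#'   primary-only LOH window fractions (targeted mode).
#' @param trunk_fraction genome fraction receiving shared trunk events
#'   (targeted mode).
#' @param wgd_met,wgd_primary double the metastasis / primary branch.
#' @param wgd_order `"late"` (trunk, branch events, then doubling; default)
#'   or `"early"` (doubling before branch events).
#' @param loh_bias probability that a loss event removes a minor-allele copy.
#' @param snap_to_windows snap targeted-mode block boundaries to the window
#'   grid (makes planted budgets exact at window resolution).
#' @param seed optional integer seed applied at the start of
#'   [simulate_pair()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(layout = default_layout(), window_size = 10000,
                              trunk_event_rate = 60,
                              branch_event_rates = c(primary = 25, met = 25),
                              event_length = c(min = 5e4, max = 5e5),
                              event_type_weights = c(loss = 0.30, gain = 0.35,
                                                     amp = 0.05, homdel = 0.05,
                                                     cn_loh = 0.25),
                              target_discordance = "free",
                              loh_met_fraction = 0.03,
                              loh_primary_fraction = 0.05,
                              trunk_fraction = 0.10,
                              wgd_met = FALSE, wgd_primary = FALSE,
                              wgd_order = c("late", "early"),
                              loh_bias = 0.6, snap_to_windows = TRUE,
                              seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  wgd_order <- match.arg(wgd_order)
  if (any(c(trunk_event_rate, branch_event_rates) < 0)) {
    stop2("simulation_config: event rates must be >= 0")
  }
  if (length(branch_event_rates) != 2L) {
    stop2("simulation_config: branch_event_rates must have 2 entries")
  }
  if (is.null(names(branch_event_rates))) {
    names(branch_event_rates) <- c("primary", "met")
  }
  if (any(event_type_weights < 0) || sum(event_type_weights) <= 0) {
    stop2("simulation_config: event_type_weights must be non-negative")
  }
  event_type_weights <- event_type_weights / sum(event_type_weights)
  if (!identical(target_discordance, "free")) {
    if (!is.numeric(target_discordance) || length(target_discordance) != 1L ||
        is.na(target_discordance) || target_discordance < 0 ||
        target_discordance > 1) {
      stop2("simulation_config: target_discordance must be 'free' or in [0, 1]")
    }
  }
  for (f in c(loh_met_fraction, loh_primary_fraction, trunk_fraction)) {
    if (f < 0 || f > 1) stop2("simulation_config: fractions must be in [0, 1]")
  }
  structure(list(layout = layout, window_size = window_size,
                 trunk_event_rate = trunk_event_rate,
                 branch_event_rates = branch_event_rates,
                 event_length = unname(event_length),
                 event_type_weights = event_type_weights,
                 target_discordance = target_discordance,
                 loh_met_fraction = loh_met_fraction,
                 loh_primary_fraction = loh_primary_fraction,
                 trunk_fraction = trunk_fraction,
                 wgd_met = wgd_met, wgd_primary = wgd_primary,
                 wgd_order = wgd_order, loh_bias = loh_bias,
                 snap_to_windows = snap_to_windows, seed = seed),
            class = "simulation_config")
}

## ---- allele-count state machinery -------------------------------------
## a = major-allele copies, b = minor-allele copies (a >= b >= 0)

.state_init <- function(layout) {
  data.frame(chromosome = layout$chromosome, start = 0,
             end = as.numeric(layout$length), a = 1, b = 1,
             stringsAsFactors = FALSE)
}

# apply fn(a, b) -> c(a, b) over [s, e) on one chromosome, splitting rows
.state_apply <- function(st, chrom, s, e, fn) {
  hit <- which(st$chromosome == chrom & st$start < e & st$end > s)
  if (!length(hit)) return(st)
  pieces <- lapply(hit, function(i) {
    r <- st[i, ]
    out <- list()
    if (r$start < s) {
      out[[length(out) + 1L]] <- data.frame(chromosome = chrom,
                                            start = r$start, end = s,
                                            a = r$a, b = r$b)
    }
    ab <- fn(r$a, r$b)
    out[[length(out) + 1L]] <- data.frame(chromosome = chrom,
                                          start = max(r$start, s),
                                          end = min(r$end, e),
                                          a = ab[1], b = ab[2])
    if (r$end > e) {
      out[[length(out) + 1L]] <- data.frame(chromosome = chrom, start = e,
                                            end = r$end, a = r$a, b = r$b)
    }
    do.call(rbind, out)
  })
  st <- rbind(st[-hit, , drop = FALSE], do.call(rbind, pieces))
  rownames(st) <- NULL
  st
}

.state_merge <- function(st, layout) {
  st <- st[order(match(st$chromosome, layout$chromosome), st$start), ,
           drop = FALSE]
  if (nrow(st) > 1) {
    same <- st$chromosome[-1] == st$chromosome[-nrow(st)] &
      st$start[-1] == st$end[-nrow(st)] &
      st$a[-1] == st$a[-nrow(st)] & st$b[-1] == st$b[-nrow(st)]
    grp <- cumsum(c(TRUE, !same))
    st <- data.frame(chromosome = tapply(st$chromosome, grp, `[`, 1),
                     start = as.numeric(tapply(st$start, grp, min)),
                     end = as.numeric(tapply(st$end, grp, max)),
                     a = as.numeric(tapply(st$a, grp, `[`, 1)),
                     b = as.numeric(tapply(st$b, grp, `[`, 1)),
                     stringsAsFactors = FALSE)
    st <- st[order(match(st$chromosome, layout$chromosome), st$start), ,
             drop = FALSE]
    rownames(st) <- NULL
  }
  st
}

.state_to_profile <- function(st, layout, sample_id, role, purity = NA_real_) {
  st <- .state_merge(st, layout)
  seg <- data.frame(chromosome = st$chromosome, start = st$start,
                    end = st$end, total_cn = st$a + st$b, minor_cn = st$b,
                    stringsAsFactors = FALSE)
  segmented_profile(sample_id, seg, role = role, purity = purity,
                    layout = layout)
}

.norm_ab <- function(a, b) c(max(a, b), min(a, b))

.fn_loss <- function(remove_minor) {
  function(a, b) {
    if (a + b == 0) return(c(0, 0))
    if (remove_minor && b > 0) b <- b - 1 else a <- max(a - 1, 0)
    .norm_ab(a, b)
  }
}
.fn_gain <- function(k = 1) function(a, b) c(a + k, b)
.fn_homdel <- function(a, b) c(0, 0)
.fn_cnloh <- function(a, b) c(a + b, 0)   # total preserved, minor removed
.fn_double <- function(a, b) c(2 * a, 2 * b)

.state_double <- function(st) {
  st$a <- 2 * st$a
  st$b <- 2 * st$b
  st
}

## ---- event drawing ----------------------------------------------------

# random event intervals; chromosomes weighted by length
.draw_events <- function(layout, n, len_range) {
  if (n == 0L) {
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric()))
  }
  ci <- sample.int(nrow(layout), n, replace = TRUE,
                   prob = layout$length / sum(layout$length))
  len <- round(exp(runif(n, log(len_range[1]), log(len_range[2]))))
  clen <- layout$length[ci]
  len <- pmin(len, clen)
  start <- floor(runif(n, 0, clen - len + 1))
  data.frame(chromosome = layout$chromosome[ci], start = start,
             end = start + len, stringsAsFactors = FALSE)
}

.apply_typed_events <- function(st, events, types, loh_bias) {
  for (i in seq_len(nrow(events))) {
    fn <- switch(types[i],
                 loss = .fn_loss(runif(1) < loh_bias),
                 gain = .fn_gain(1),
                 amp = .fn_gain(4),
                 homdel = .fn_homdel,
                 cn_loh = .fn_cnloh,
                 gain1 = .fn_gain(1),
                 gain2 = .fn_gain(2),
                 stop2("unknown event type %s", types[i]))
    st <- .state_apply(st, events$chromosome[i], events$start[i],
                       events$end[i], fn)
  }
  st
}

## ---- targeted-mode block planting -------------------------------------

# partition the genome into blocks with log-uniform lengths
.draw_blocks <- function(layout, len_range, window_size, snap = TRUE) {
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    lens <- numeric(0)
    total <- 0
    while (total < len) {
      l <- exp(runif(1, log(len_range[1]), log(len_range[2])))
      l <- if (snap) max(window_size, round(l / window_size) * window_size)
        else max(1, round(l))
      l <- min(l, len - total)
      lens <- c(lens, l)
      total <- total + l
    }
    start <- cumsum(c(0, lens[-length(lens)]))
    data.frame(chromosome = layout$chromosome[i], start = start,
               end = start + lens, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.mark_hotspots <- function(blocks, fraction) {
  w <- blocks$end - blocks$start
  ord <- sample.int(nrow(blocks))
  cum <- cumsum(w[ord])
  k <- which(cum >= fraction * sum(w))[1]
  if (is.na(k)) k <- length(ord)
  flag <- logical(nrow(blocks))
  flag[ord[seq_len(k)]] <- TRUE
  blocks$hotspot <- flag
  blocks
}

# allocate disjoint blocks to event classes to meet bp budgets; recurrent
# classes draw from hotspot blocks first so that private events recur at the
# same loci across pairs
.plant_blocks <- function(blocks, budgets, window_size, snap = TRUE) {
  if (is.null(blocks$hotspot)) blocks$hotspot <- TRUE
  avail_h <- sample(which(blocks$hotspot))
  avail_o <- sample(which(!blocks$hotspot))
  take <- function(budget, pools) {
    out <- list()
    for (p in seq_along(pools)) {
      pool <- pools[[p]]
      while (budget > 0 && length(pool)) {
        i <- pool[1]
        pool <- pool[-1]
        b <- blocks[i, c("chromosome", "start", "end")]
        w <- b$end - b$start
        if (w > budget) {
          keep <- if (snap) floor(budget / window_size) * window_size else budget
          if (keep <= 0) next
          b$end <- b$start + keep
          w <- keep
        }
        out[[length(out) + 1L]] <- b
        budget <- budget - w
      }
      pools[[p]] <- pool
    }
    list(rows = if (length(out)) do.call(rbind, out) else NULL, pools = pools)
  }
  res <- list()
  pools <- list(h = avail_h, o = avail_o)
  for (cls in c("cn", "loh_met", "loh_primary")) {
    t <- take(budgets[[cls]], pools)
    pools <- t$pools
    if (!is.null(t$rows)) {
      t$rows$class <- cls
      res[[length(res) + 1L]] <- t$rows
    }
  }
  # trunk events prefer non-recurrent territory
  t <- take(budgets[["trunk"]], list(pools$o, pools$h))
  if (!is.null(t$rows)) {
    t$rows$class <- "trunk"
    res[[length(res) + 1L]] <- t$rows
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(chromosome = character(), start = numeric(), end = numeric(),
               class = character())
}

## ---- pair simulation --------------------------------------------------

#' Simulate one paired primary/metastasis profile with ground truth
#'
#' See [simulation_config()] for the two generation modes. Ground truth is
#' recomputed from the emitted profiles with [pair_ground_truth()] (the
#' generator's independent measurement path).
#'
#' @param config a [simulation_config()].
#' @param patient_id patient label; sample ids are `<patient>-T` and
#'   `<patient>-M`.
#' @param blocks optional pre-drawn block partition (data frame from the
#'   internal block drawer, possibly with a `hotspot` column); lets a cohort
#'   share recurrent event loci across pairs. Targeted mode only.
#' @param gene_amp optional data frame (`chromosome`, `start`, `end`) of
#'   intervals given a +5 copy metastasis-private amplification (e.g. a
#'   planted actionable-gene amplification).
#' @param genes optional gene table; when given, per-gene ground-truth
#'   labels are attached.
#' @return list with `primary`, `met` ([segmented_profile()]s) and `truth`.
#' @examples
#' cfg <- simulation_config(layout = default_layout(4, 1e6),
#'                          target_discordance = 0.2, seed = 7)
#' sim <- simulate_pair(cfg, "P1")
#' sim$truth$window$cn_discordant_fraction
#' @export
simulate_pair <- function(config = simulation_config(), patient_id = "P1",
                          blocks = NULL, gene_amp = NULL, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  layout <- config$layout
  targeted <- !identical(config$target_discordance, "free")
  st0 <- .state_init(layout)
  planted <- NULL

  if (targeted) {
    if (config$wgd_primary && !config$wgd_met) {
      stop2(paste0("simulate_pair: target_discordance is infeasible with ",
                   "primary-only WGD: every window carries a negative diff ",
                   "the +1/+2 metastasis-gain correction never forgives"))
    }
    G <- genome_size(layout)
    xor_wgd <- xor(config$wgd_met, config$wgd_primary)
    d_cn <- config$target_discordance -
      (if (xor_wgd) config$loh_met_fraction + config$loh_primary_fraction
       else 0)
    if (d_cn < -1e-9) {
      stop2(paste0("simulate_pair: target_discordance %.3f infeasible: with ",
                   "WGD on one branch the planted LOH fractions (%.3f met + ",
                   "%.3f primary) are themselves CN-discordant and exceed ",
                   "the target"), config$target_discordance,
            config$loh_met_fraction, config$loh_primary_fraction)
    }
    d_cn <- max(d_cn, 0)
    total_plant <- d_cn + config$loh_met_fraction +
      config$loh_primary_fraction + config$trunk_fraction
    if (total_plant > 0.95) {
      stop2("simulate_pair: planted fractions total %.2f > 0.95 of the genome",
            total_plant)
    }
    snap_bp <- function(f) {
      round(f * G / config$window_size) * config$window_size
    }
    budgets <- list(cn = snap_bp(d_cn),
                    loh_met = snap_bp(config$loh_met_fraction),
                    loh_primary = snap_bp(config$loh_primary_fraction),
                    trunk = snap_bp(config$trunk_fraction))
    if (is.null(blocks)) {
      blocks <- .draw_blocks(layout, config$event_length, config$window_size,
                             snap = config$snap_to_windows)
    }
    plan <- .plant_blocks(blocks, budgets, config$window_size,
                          snap = config$snap_to_windows)
    planted <- plan
    # shared trunk events; in WGD-asymmetric pairs restrict to types whose
    # post-doubling diff (+1/+2, LOH unchanged) is forgiven by the correction
    trunk <- plan[plan$class == "trunk", , drop = FALSE]
    if (nrow(trunk)) {
      types <- if (xor_wgd) {
        sample(c("loss", "cn_loh"), nrow(trunk), replace = TRUE,
               prob = c(0.55, 0.45))
      } else {
        sample(c("gain1", "gain2", "loss", "cn_loh"), nrow(trunk),
               replace = TRUE, prob = c(0.35, 0.25, 0.20, 0.20))
      }
      st0 <- .apply_typed_events(st0, trunk, types, config$loh_bias)
    }
    p_st <- st0
    m_st <- st0
    if (config$wgd_order == "early") {
      if (config$wgd_primary) p_st <- .state_double(p_st)
      if (config$wgd_met) m_st <- .state_double(m_st)
    }
    # CN-discordant blocks, placed so the diff is never forgiven:
    #  * no WGD: +3-copy gains on the metastasis branch (diff +3);
    #  * metastasis-only WGD: +3-copy gains on the primary branch (negative
    #    diff), keeping the doubled branch at (3,4)-biallelic states;
    #  * WGD on both branches: single-copy losses on the metastasis applied
    #    *after* the doubling (diff -1; the (3,1) state still qualifies for
    #    the WGD rule on both branches).
    cnb <- plan[plan$class == "cn", , drop = FALSE]
    both_wgd <- config$wgd_met && config$wgd_primary
    if (!both_wgd) {
      for (i in seq_len(nrow(cnb))) {
        if (xor_wgd && config$wgd_met) {
          p_st <- .state_apply(p_st, cnb$chromosome[i], cnb$start[i],
                               cnb$end[i], .fn_gain(3))
        } else {
          m_st <- .state_apply(m_st, cnb$chromosome[i], cnb$start[i],
                               cnb$end[i], .fn_gain(3))
        }
      }
    }
    lm <- plan[plan$class == "loh_met", , drop = FALSE]
    for (i in seq_len(nrow(lm))) {
      m_st <- .state_apply(m_st, lm$chromosome[i], lm$start[i], lm$end[i],
                           .fn_cnloh)
    }
    lp <- plan[plan$class == "loh_primary", , drop = FALSE]
    for (i in seq_len(nrow(lp))) {
      p_st <- .state_apply(p_st, lp$chromosome[i], lp$start[i], lp$end[i],
                           .fn_cnloh)
    }
  } else {
    n_trunk <- rpois(1, config$trunk_event_rate)
    ev <- .draw_events(layout, n_trunk, config$event_length)
    types <- sample(names(config$event_type_weights), n_trunk, replace = TRUE,
                    prob = config$event_type_weights)
    st0 <- .apply_typed_events(st0, ev, types, config$loh_bias)
    p_st <- st0
    m_st <- st0
    if (config$wgd_order == "early") {
      if (config$wgd_primary) p_st <- .state_double(p_st)
      if (config$wgd_met) m_st <- .state_double(m_st)
    }
    for (branch in c("primary", "met")) {
      n_b <- rpois(1, config$branch_event_rates[[branch]])
      ev <- .draw_events(layout, n_b, config$event_length)
      types <- sample(names(config$event_type_weights), n_b, replace = TRUE,
                      prob = config$event_type_weights)
      if (branch == "primary") {
        p_st <- .apply_typed_events(p_st, ev, types, config$loh_bias)
      } else {
        m_st <- .apply_typed_events(m_st, ev, types, config$loh_bias)
      }
    }
  }

  if (!is.null(gene_amp) && nrow(gene_amp)) {
    for (i in seq_len(nrow(gene_amp))) {
      m_st <- .state_apply(m_st, gene_amp$chromosome[i], gene_amp$start[i],
                           gene_amp$end[i], .fn_gain(5))
    }
  }
  if (config$wgd_order == "late") {
    if (config$wgd_primary) p_st <- .state_double(p_st)
    if (config$wgd_met) m_st <- .state_double(m_st)
  }
  if (targeted && config$wgd_met && config$wgd_primary) {
    cnb <- planted[planted$class == "cn", , drop = FALSE]
    for (i in seq_len(nrow(cnb))) {
      m_st <- .state_apply(m_st, cnb$chromosome[i], cnb$start[i],
                           cnb$end[i], .fn_loss(FALSE))
    }
  }

  primary <- .state_to_profile(p_st, layout, paste0(patient_id, "-T"),
                               "primary", purity = runif(1, 0.5, 0.95))
  met <- .state_to_profile(m_st, layout, paste0(patient_id, "-M"),
                           "metastasis", purity = runif(1, 0.5, 0.95))
  truth <- pair_ground_truth(primary, met, layout,
                             window_size = config$window_size,
                             wgd_correction = TRUE, genes = genes)
  truth$wgd_primary <- config$wgd_primary
  truth$wgd_met <- config$wgd_met
  truth$target <- if (targeted) {
    list(cn_discordant_fraction = config$target_discordance,
         loh_met_only_fraction = config$loh_met_fraction,
         loh_primary_only_fraction = config$loh_primary_fraction)
  } else NULL
  truth$planted_blocks <- planted
  list(primary = primary, met = met, truth = truth)
}

## ---- gene panel -------------------------------------------------------

#' Simulate a candidate/actionable gene panel
#'
#' Places non-overlapping gene footprints uniformly on the layout:
#' `n_candidate` candidate genes (symbols `CANDxxx`), of which `n_both` are
#' also clinically actionable (symbols `DUALxx`, panel `both`), plus
#' `n_actionable - n_both` actionable-only genes (symbols `ACTxx`).
#'
#' @param layout a [genome_layout()].
#' @param n_candidate,n_actionable,n_both panel sizes.
#' @param gene_length footprint length in bp.
#' @return gene table as from [read_gene_annotation()].
#' @export
simulate_gene_panel <- function(layout, n_candidate = 188, n_actionable = 24,
                                n_both = 10, gene_length = 6e4) {
  n_total <- n_candidate + n_actionable - n_both
  placed <- list()
  by_chrom <- new.env()
  tries <- 0
  while (length(placed) < n_total && tries < n_total * 200) {
    tries <- tries + 1
    ci <- sample.int(nrow(layout), 1, prob = layout$length / sum(layout$length))
    ch <- layout$chromosome[ci]
    if (layout$length[ci] <= gene_length) next
    s <- floor(runif(1, 0, layout$length[ci] - gene_length))
    e <- s + gene_length
    prev <- get0(ch, envir = by_chrom, ifnotfound = NULL)
    if (!is.null(prev) && any(prev$start < e & prev$end > s)) next
    assign(ch, rbind(prev, data.frame(start = s, end = e)), envir = by_chrom)
    placed[[length(placed) + 1L]] <- data.frame(chromosome = ch, start = s,
                                                end = e)
  }
  if (length(placed) < n_total) {
    stop2("simulate_gene_panel: could not place %d non-overlapping genes",
          n_total)
  }
  df <- do.call(rbind, placed)
  n_cand_only <- n_candidate - n_both
  n_act_only <- n_actionable - n_both
  df$symbol <- c(sprintf("CAND%03d", seq_len(n_cand_only)),
                 sprintf("DUAL%02d", seq_len(n_both)),
                 sprintf("ACT%02d", seq_len(n_act_only)))
  df$panel <- rep(c("candidate188", "both", "actionable24"),
                  c(n_cand_only, n_both, n_act_only))
  validate_genes(df[, c("symbol", "chromosome", "start", "end", "panel")],
                 layout = layout)
}

## ---- cohort -----------------------------------------------------------

#' Default 16-pair cohort design
#'
#' The planted study conditions: 16 patients (10 treatment-naive and 6
#' post-therapy metastases; 9 synchronous and 7 metachronous), whole-genome
#' doubling of both samples in 4 pairs and of the metastasis only in 5, no
#' primary-only WGD. Planted CN-discordance fractions average 0.28 in the
#' naive group and 0.12 post-therapy (0.22 overall); planted LOH budgets
#' put primary-only LOH mostly in naive pairs (0.09 vs 0.02) and
#' metastasis-only LOH mostly post-therapy (0.11 vs 0.03), an average
#' paired LOH difference of 0.124. Four patients carry a planted
#' metastasis-private amplification of one actionable gene each.
#'
#' @return design data frame, one row per pair.
#' @export
default_cohort_design <- function() {
  d <- data.frame(
    patient_id = sprintf("C%02d", 1:16),
    timing = c("metachronous", "metachronous", "metachronous", "synchronous",
               "synchronous", "metachronous", "metachronous", "metachronous",
               "synchronous", "metachronous", "synchronous", "synchronous",
               "synchronous", "synchronous", "synchronous", "synchronous"),
    met_exposure = c("post_therapy", "post_therapy", "post_therapy",
                     "post_therapy", "naive", "post_therapy", "naive",
                     "post_therapy", "naive", "naive", "naive", "naive",
                     "naive", "naive", "naive", "naive"),
    wgd_primary = FALSE,
    wgd_met = FALSE,
    target_discordance = c(0.18, 0.09, 0.16, 0.10, 0.46, 0.05, 0.28, 0.14,
                           0.44, 0.36, 0.30, 0.24, 0.22, 0.20, 0.14, 0.16),
    met_private_amp_gene = NA_character_,
    stringsAsFactors = FALSE)
  d$wgd_primary[d$patient_id %in% c("C02", "C12", "C14", "C15")] <- TRUE
  d$wgd_met[d$patient_id %in% c("C02", "C03", "C08", "C11", "C12", "C13",
                                "C14", "C15", "C16")] <- TRUE
  naive <- d$met_exposure == "naive"
  d$loh_met_fraction <- ifelse(naive, 0.03, 0.11)
  d$loh_primary_fraction <- ifelse(naive, 0.09, 0.02)
  amp_patients <- c("C06", "C08", "C04", "C13")
  d$met_private_amp_gene[match(amp_patients, d$patient_id)] <-
    sprintf("ACT%02d", 1:4)
  d
}

#' Simulate a paired cohort with shared recurrent event loci
#'
#' Draws one genome-wide block partition per cohort and marks a
#' `hotspot_fraction` of it as recurrent territory from which every pair's
#' private events are drawn first, so that discordant loci recur across
#' pairs (as driver-gene regions do in real cohorts). Per-pair planted
#' budgets are the design values jittered multiplicatively
#' (`exp(N(0, jitter_sd))`, mean-corrected) to emulate biological spread.
#'
#' @param design design data frame as from [default_cohort_design()].
#' @param layout a [genome_layout()].
#' @param window_size window size in bp.
#' @param seed integer seed for the whole cohort draw.
#' @param genes optional gene table; simulated with
#'   [simulate_gene_panel()] when `NULL`.
#' @param hotspot_fraction genome fraction of recurrent territory.
#' @param jitter_sd log-scale standard deviation of per-pair budget jitter
#'   (0 disables jitter).
#' @param event_length block length range, bp.
#' @param trunk_fraction shared trunk event budget per pair.
#' @param outdir optional directory; when given, all cohort files are
#'   written there in the package's file dialects (per-sample profile TSVs,
#'   chrom sizes, gene BED, sample sheet, ground-truth TSV).
#' @return list with `profiles` (named by sample id), `sheet`, `genes`,
#'   `truths` (named by patient), `design` (realized budgets), `layout`.
#' @export
simulate_cohort <- function(design = default_cohort_design(),
                            layout = default_layout(), window_size = 10000,
                            seed = NULL, genes = NULL,
                            hotspot_fraction = 0.5, jitter_sd = 0.15,
                            event_length = c(5e4, 5e5),
                            trunk_fraction = 0.10, outdir = NULL) {
  if (nrow(design) < 1L) stop2("simulate_cohort: need at least one pair")
  need <- c("patient_id", "timing", "met_exposure", "wgd_primary", "wgd_met",
            "target_discordance", "loh_met_fraction", "loh_primary_fraction")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop2("simulate_cohort: design lacks column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$patient_id)) {
    stop2("simulate_cohort: duplicate patient_id in design")
  }
  if (any(!design$timing %in% c("synchronous", "metachronous"))) {
    stop2("simulate_cohort: design timing must be synchronous/metachronous")
  }
  if (any(!design$met_exposure %in% c("naive", "post_therapy"))) {
    stop2("simulate_cohort: design met_exposure must be naive/post_therapy")
  }
  if (is.null(design$met_private_amp_gene)) {
    design$met_private_amp_gene <- rep(NA_character_, nrow(design))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- simulate_gene_panel(layout)
  blocks <- .draw_blocks(layout, event_length, window_size, snap = TRUE)
  blocks <- .mark_hotspots(blocks, hotspot_fraction)
  jit <- function(x) {
    if (jitter_sd <= 0) return(x)
    x * exp(rnorm(length(x), 0, jitter_sd) - jitter_sd^2 / 2)
  }
  profiles <- list()
  truths <- list()
  sheet_rows <- list()
  realized <- design
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    d <- min(max(jit(row$target_discordance), 0.02), 0.90)
    f_m <- min(max(jit(row$loh_met_fraction), 0.005), 0.30)
    f_p <- min(max(jit(row$loh_primary_fraction), 0.005), 0.30)
    if (xor(row$wgd_met, row$wgd_primary)) d <- max(d, f_m + f_p + 0.002)
    cfg <- simulation_config(layout = layout, window_size = window_size,
                             target_discordance = d, loh_met_fraction = f_m,
                             loh_primary_fraction = f_p,
                             trunk_fraction = trunk_fraction,
                             event_length = event_length,
                             wgd_met = row$wgd_met,
                             wgd_primary = row$wgd_primary)
    gene_amp <- NULL
    if (!is.na(row$met_private_amp_gene)) {
      g <- genes[genes$symbol == row$met_private_amp_gene, , drop = FALSE]
      if (nrow(g) == 0L) {
        stop2("simulate_cohort: planted amp gene %s not in the panel",
              row$met_private_amp_gene)
      }
      # cover the footprint fully, snapped outward to window boundaries
      gene_amp <- data.frame(
        chromosome = g$chromosome,
        start = floor(g$start / window_size) * window_size,
        end = pmin(ceiling(g$end / window_size) * window_size,
                   layout$length[match(g$chromosome, layout$chromosome)]))
    }
    sim <- simulate_pair(cfg, row$patient_id, blocks = blocks,
                         gene_amp = gene_amp, genes = genes)
    profiles[[sim$primary$sample_id]] <- sim$primary
    profiles[[sim$met$sample_id]] <- sim$met
    truths[[row$patient_id]] <- sim$truth
    realized$target_discordance[i] <- d
    realized$loh_met_fraction[i] <- f_m
    realized$loh_primary_fraction[i] <- f_p
    sheet_rows[[i]] <- data.frame(
      patient_id = row$patient_id,
      primary_sample = sim$primary$sample_id,
      met_sample = sim$met$sample_id,
      timing = row$timing, met_exposure = row$met_exposure,
      purity_primary = sim$primary$purity, purity_met = sim$met$purity,
      stringsAsFactors = FALSE)
  }
  sheet <- validate_sample_sheet(do.call(rbind, sheet_rows))
  out <- list(profiles = profiles, sheet = sheet, genes = genes,
              truths = truths, design = realized, layout = layout,
              window_size = window_size)
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

#' Write a simulated cohort to disk in the package's file dialects
#'
#' @param cohort result of [simulate_cohort()].
#' @param outdir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(cohort$layout, file.path(outdir, "chrom_sizes.tsv"))
  write_gene_annotation(cohort$genes, file.path(outdir, "genes.bed"))
  write_sample_sheet(cohort$sheet, file.path(outdir, "sample_sheet.tsv"))
  dir.create(file.path(outdir, "profiles"), showWarnings = FALSE)
  for (p in cohort$profiles) {
    write_profile(p, file.path(outdir, "profiles",
                               paste0(p$sample_id, ".seg.tsv")))
  }
  tr <- do.call(rbind, lapply(names(cohort$truths), function(pid) {
    t <- cohort$truths[[pid]]
    data.frame(patient_id = pid,
               cn_discordant_fraction = t$window$cn_discordant_fraction,
               loh_met_only_fraction = t$window$loh_met_only_fraction,
               loh_primary_only_fraction = t$window$loh_primary_only_fraction,
               cn_discordant_fraction_uncorrected =
                 t$window_uncorrected$cn_discordant_fraction,
               wgd_primary = t$wgd_primary, wgd_met = t$wgd_met,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tr, file.path(outdir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Draw cohort metric tables for statistical calibration
#'
#' Emulates per-pair discordance metrics at the cohort-table level (normal
#' draws around group means, clamped to \[0, 1\]) without simulating
#' profiles; used to calibrate [compare_groups()] over many replicate
#' cohorts.
#'
#' @param n_naive,n_post group sizes.
#' @param mean_naive,mean_post group means of the metric.
#' @param sd within-group standard deviation.
#' @param metric name of the metric column to produce.
#' @return data frame with `met_exposure`, `timing` and the metric column.
#' @export
simulate_cohort_metrics <- function(n_naive = 10, n_post = 6,
                                    mean_naive = 0.22, mean_post = 0.22,
                                    sd = 0.06,
                                    metric = "cn_discordant_fraction") {
  g <- rep(c("naive", "post_therapy"), c(n_naive, n_post))
  x <- rnorm(n_naive + n_post, ifelse(g == "naive", mean_naive, mean_post),
             sd)
  out <- data.frame(met_exposure = g,
                    timing = sample(c("synchronous", "metachronous"),
                                    n_naive + n_post, replace = TRUE),
                    stringsAsFactors = FALSE)
  out[[metric]] <- pmin(pmax(x, 0), 1)
  out
}
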