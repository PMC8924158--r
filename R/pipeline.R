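# End-to-end orchestration: run configuration, the demo cohort pipeline
# (simulate -> entrainment -> ERP -> reports), and run-time persistence.

#' Run configuration for the demo cohort
#'
#' All analysis and simulation knobs in one serializable list. The
#' default cohort is 20 subjects on a 32-channel montage (the analysis is
#' channel-count agnostic; 32 channels keep the full pipeline within a
#' one-CPU desk budget).
#'
#' @param n_subjects Simulated subjects (default 20).
#' @param n_channels Electrodes (default 32).
#' @param head_radius cm (default 6).
#' @param lists Stimulus lists cycled over subjects.
#' @param sim Named list of [simulation_config()] overrides.
#' @param reject_threshold uV.
#' @param q FDR level.
#' @param n_pca,n_dss DSS dimensions (capped at `n_channels`).
#' @param min_segments,min_trials Subject inclusion thresholds.
#' @param windows ERP search windows (list of `c(start, end)` s).
#' @param n_perm Cluster permutations for the demo (default 1000; the
#'   [cluster_permutation()] default remains 5000).
#' @param sliding_step_s Step of the demo's sliding analysis (default
#'   30 s to fit a one-CPU budget; 1.5 s at full resolution).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 20L, n_channels = 32L, head_radius = 6,
                       lists = c("A", "B", "C"),
                       sim = list(), reject_threshold = 400, q = 0.05,
                       n_pca = 30L, n_dss = 6L,
                       min_segments = 6L, min_trials = 12L,
                       windows = list(early = c(0, 0.5),
                                      late = c(0.5, 2.75)),
                       n_perm = 1000L, sliding_step_s = 30,
                       seed = 0L) {
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 head_radius = head_radius, lists = lists, sim = sim,
                 reject_threshold = reject_threshold, q = q,
                 n_pca = min(as.integer(n_pca), as.integer(n_channels)),
                 n_dss = as.integer(n_dss),
                 min_segments = as.integer(min_segments),
                 min_trials = as.integer(min_trials),
                 windows = windows, n_perm = as.integer(n_perm),
                 sliding_step_s = sliding_step_s,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `path` / a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$windows <- lapply(x$windows, as.numeric)
  do.call(run_config, x)
}

# Short md5 digest identifying a configuration; stamped on every output
# table.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}

#' Persist / restore an epoch set (run-time container)
#'
#' Base-R serialization stands in for an HDF5 container (no HDF5 R
#' bindings are available); files are run-time artifacts, not exchange
#' format.
#'
#' @param epochs An `epoch_set`.
#' @param path File path.
#' @return `path` / the `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readRDS(path)
  if (!inherits(x, "epoch_set")) stopf("%s does not hold an epoch_set", path)
  x
}

.simulate_subject <- function(config, s, montage) {
  list_id <- config$lists[(s - 1L) %% length(config$lists) + 1L]
  lex <- build_lexicon(list_id)
  sched <- build_session_schedule(lex, seed = derive_seed(config$seed,
                                                          1000L + s))
  sim_args <- config$sim
  sim_args$seed <- derive_seed(config$seed, 2000L + s)
  sim_cfg <- do.call(simulation_config, sim_args)
  simulate_recording(sched, montage, sim_cfg)
}

#' Run the end-to-end demo cohort
#'
#' Simulates `config$n_subjects` sessions, runs the per-condition and
#' sliding-window entrainment analyses and the ERP cluster contrasts, and
#' writes TSV reports (plus advisory PDF figures) to `out_dir`. Every
#' table carries the config hash; per-stage retention and exclusions are
#' logged. Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @param sliding Also compute the sliding-window time course (slowest
#'   stage; default TRUE).
#' @param figures Write advisory PDF figures (default TRUE).
#' @return Invisibly, a list with the collected results and output paths.
#' @export
run_demo_cohort <- function(config = run_config(), out_dir = "demo_out",
                            sliding = TRUE, figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_run_config(config, file.path(out_dir, "config.json"))
  montage <- make_montage(config$n_channels, config$head_radius,
                          seed = config$seed)
  adjacency <- build_adjacency(montage, max_dist = 3)
  conds <- c("RestingState", "Random", "Structured")
  rates <- c("word", "syllable")
  ns <- config$n_subjects
  n_ch <- config$n_channels
  snr_p <- array(NA_real_, c(ns, n_ch, 3L, 2L),
                 dimnames = list(NULL, montage$channels, conds, rates))
  snr_i <- snr_p
  erp_avgs <- vector("list", ns)
  block_avgs <- vector("list", ns)
  slide_p <- NULL; slide_i <- NULL; centers <- NULL
  erp_times <- NULL
  excluded <- character()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "entrainr_excluded")) stop(e)
      stopf("stage '%s' failed: %s", what, conditionMessage(e))
    })
  }

  for (s in seq_len(ns)) {
    message(sprintf("[demo] subject %d/%d", s, ns))
    rec <- stage("simulate", .simulate_subject(config, s, montage))
    ent_ep <- stage("preprocess-entrainment",
                    preprocess_entrainment(rec, config$reject_threshold))
    for (ci in seq_along(conds)) {
      res <- tryCatch(
        condition_entrainment(rec, conds[ci],
                              n_pca = config$n_pca, n_dss = config$n_dss,
                              epochs = ent_ep,
                              min_segments = config$min_segments),
        entrainr_excluded = function(e) {
          excluded <<- c(excluded, sprintf("s%d/%s: %s", s, conds[ci],
                                           conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) {
        snr_p[s, , ci, ] <- res$snr_power
        snr_i[s, , ci, ] <- res$snr_itc
      }
    }
    if (sliding) {
      sl <- stage("sliding",
                  sliding_entrainment(rec, step_s = config$sliding_step_s,
                                      n_pca = config$n_pca,
                                      n_dss = config$n_dss,
                                      epochs = ent_ep))
      if (is.null(slide_p)) {
        centers <- sl$centers
        slide_p <- array(NA_real_, c(ns, length(centers), 2L))
        slide_i <- slide_p
      }
      k <- min(length(centers), length(sl$centers))
      slide_p[s, seq_len(k), ] <- apply(sl$snr_power, c(1L, 3L),
                                        mean)[seq_len(k), ]
      slide_i[s, seq_len(k), ] <- apply(sl$snr_itc, c(1L, 3L),
                                        mean)[seq_len(k), ]
    }
    erp_ep <- stage("preprocess-erp",
                    preprocess_erp(rec, config$reject_threshold))
    if (is.null(erp_times)) erp_times <- epoch_times(erp_ep)
    sce <- tryCatch(
      subject_condition_erps(erp_ep, min_trials = config$min_trials),
      entrainr_excluded = function(e) {
        excluded <<- c(excluded, sprintf("s%d/erp: %s", s,
                                         conditionMessage(e)))
        NULL
      })
    erp_avgs[[s]] <- sce
    # per-block side averages for the block time course
    if (!is.null(sce)) {
      blocks <- sort(unique(erp_ep$metadata$block))
      ba <- list()
      for (b in blocks) {
        for (side in c("a", "b")) {
          lab <- if (side == "a") c("Word", "EdgeWord") else
            c("PartWord", "NonWord")
          selb <- erp_ep$metadata$block == b &
            erp_ep$metadata$condition %in% lab
          ba[[sprintf("b%d_%s", b, side)]] <- list(
            n = sum(selb),
            avg = if (sum(selb))
              colMeans(erp_ep$data[selb, , , drop = FALSE], dims = 1L)
            else NULL)
        }
      }
      block_avgs[[s]] <- ba
    }
    rm(rec, ent_ep, erp_ep); gc(FALSE)
  }

  # ---- entrainment group statistics ----------------------------------
  snr_rows <- list(); test_rows <- list(); anova_rows <- list()
  for (ci in seq_along(conds)) {
    for (ri in seq_along(rates)) {
      keep <- stats::complete.cases(snr_p[, 1L, ci, ri])
      snr_rows[[length(snr_rows) + 1L]] <- data.frame(
        subject = rep(which(keep), each = n_ch),
        condition = conds[ci], rate = rates[ri],
        channel = rep(montage$channels, sum(keep)),
        snr_power = as.vector(t(snr_p[keep, , ci, ri])),
        snr_itc = as.vector(t(snr_i[keep, , ci, ri])))
      if (sum(keep) < 2L) next          # group tests need >= 2 subjects
      et <- electrode_tests(snr_p[keep, , ci, ri], config$q)
      et$condition <- conds[ci]; et$rate <- rates[ri]; et$measure <- "power"
      ei <- electrode_tests(snr_i[keep, , ci, ri], config$q)
      ei$condition <- conds[ci]; ei$rate <- rates[ri]; ei$measure <- "itc"
      test_rows[[length(test_rows) + 1L]] <- rbind(et, ei)
    }
  }
  anovas <- list()
  for (ri in seq_along(rates)) {
    for (meas in c("power", "itc")) {
      arr <- if (meas == "power") snr_p else snr_i
      keep <- stats::complete.cases(arr[, 1L, 1L, ri] + arr[, 1L, 2L, ri] +
                                      arr[, 1L, 3L, ri])
      if (sum(keep) < 3L) next          # repeated-measures ANOVA needs >= 3
      byc <- stats::setNames(lapply(seq_along(conds), function(ci)
        matrix(arr[keep, , ci, ri], nrow = sum(keep),
               dimnames = list(NULL, montage$channels))), conds)
      ca <- condition_anova(byc, config$q)
      anovas[[paste(rates[ri], meas, sep = "_")]] <- ca
      if (!is.null(ca$anova)) {
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          rate = rates[ri], measure = meas, F = ca$anova$F,
          df_num = ca$anova$df_num, df_den = ca$anova$df_den,
          p = ca$anova$p, n_electrodes = length(ca$electrodes),
          post_hoc = paste(sprintf("%s-%s:%.4g", ca$anova$post_hoc$a,
                                   ca$anova$post_hoc$b,
                                   ca$anova$post_hoc$p_bonferroni),
                           collapse = ";"))
      }
    }
  }

  # ---- ERP cluster contrasts -----------------------------------------
  keep_erp <- which(!vapply(erp_avgs, is.null, TRUE))
  cluster_rows <- list(); block_rows <- list(); cluster_tests <- list()
  if (length(keep_erp) >= 2L) {
    for (cname in c("abx-bcx", "heard-unheard")) {
      cs <- contrast_spec(cname)
      a <- b <- array(0, c(length(keep_erp), n_ch, length(erp_times)))
      for (j in seq_along(keep_erp)) {
        e <- erp_avgs[[keep_erp[j]]]$erps
        a[j, , ] <- colMeans(e[cs$side_a, , , drop = FALSE], dims = 1L)
        b[j, , ] <- colMeans(e[cs$side_b, , , drop = FALSE], dims = 1L)
      }
      for (wname in names(config$windows)) {
        ct <- stage("cluster-permutation",
                    cluster_permutation(a, b, adjacency, erp_times,
                                        window = config$windows[[wname]],
                                        n_perm = config$n_perm,
                                        seed = derive_seed(config$seed,
                                                           3000L)))
        cluster_tests[[paste(cname, wname, sep = "/")]] <- ct
        if (nrow(ct$clusters)) {
          cdf <- ct$clusters
          cdf$contrast <- cname; cdf$window <- wname
          cluster_rows[[length(cluster_rows) + 1L]] <- cdf
        }
        # block time course over the best early ABx-BCx cluster
        if (cname == "abx-bcx" && wname == "early" && nrow(ct$clusters)) {
          pts <- ct$points[[1L]]
          sel_t <- which(erp_times >= ct$window[1] &
                           erp_times <= ct$window[2])
          for (j in seq_along(keep_erp)) {
            ba <- block_avgs[[keep_erp[j]]]
            for (bl in 1:8) {
              na_ <- ba[[sprintf("b%d_a", bl)]]; nb_ <- ba[[sprintf("b%d_b", bl)]]
              if (is.null(na_) || na_$n < 3L || nb_$n < 3L) next
              dm <- (na_$avg - nb_$avg)[, sel_t, drop = FALSE]
              block_rows[[length(block_rows) + 1L]] <- data.frame(
                subject = keep_erp[j], block = bl, effect = mean(dm[pts]))
            }
          }
        }
      }
    }
  }

  # ---- write reports --------------------------------------------------
  stamp <- function(df) { df$config_hash <- hash; df }
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(stamp(df), p)
    paths[[name]] <<- p
  }
  wr(do.call(rbind, snr_rows), "entrainment_snr.tsv")
  wr(do.call(rbind, test_rows), "entrainment_tests.tsv")
  if (length(anova_rows)) wr(do.call(rbind, anova_rows), "anova.tsv")
  if (sliding && !is.null(slide_p)) {
    sl_rows <- list()
    for (ri in 1:2) {
      m <- matrix(slide_p[, , ri], nrow = dim(slide_p)[1])
      keep <- stats::complete.cases(m)
      sig <- if (sum(keep) >= 2L) {
        electrode_tests(m[keep, , drop = FALSE], config$q)$significant
      } else {
        rep(NA, length(centers))
      }
      sl_rows[[ri]] <- data.frame(center_s = centers, rate = rates[ri],
                                  mean_snr_power = colMeans(m[keep, ,
                                                              drop = FALSE]),
                                  significant = sig)
    }
    wr(do.call(rbind, sl_rows), "sliding_time_course.tsv")
  }
  if (length(cluster_rows)) {
    wr(do.call(rbind, cluster_rows), "erp_clusters.tsv")
  }
  if (length(block_rows)) {
    wr(do.call(rbind, block_rows), "block_time_course.tsv")
  }
  log_lines <- c(sprintf("config_hash: %s", hash),
                 sprintf("subjects: %d", ns),
                 sprintf("excluded: %s",
                         if (length(excluded))
                           paste(excluded, collapse = "; ") else "none"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  if (figures) {
    .demo_figures(out_dir, conds, rates, snr_p, centers, slide_p,
                  cluster_tests, erp_times)
  }
  invisible(list(snr_power = snr_p, snr_itc = snr_i,
                 sliding_centers = centers, sliding_power = slide_p,
                 anovas = anovas, cluster_tests = cluster_tests,
                 excluded = excluded, paths = paths, hash = hash,
                 montage = montage))
}

# Advisory figures (not part of any acceptance surface).
.demo_figures <- function(out_dir, conds, rates, snr_p, centers, slide_p,
                          cluster_tests, erp_times) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 8, height = 5)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2))
  for (ri in 1:2) {
    m <- apply(snr_p[, , , ri, drop = FALSE], 3L, mean, na.rm = TRUE)
    graphics::barplot(m, names.arg = substr(conds, 1, 4),
                      main = sprintf("SNR(power), %s rate", rates[ri]),
                      ylab = "mean SNR")
  }
  graphics::par(op)
  if (!is.null(slide_p)) {
    for (ri in 1:2) {
      m <- colMeans(slide_p[, , ri, drop = FALSE][, , 1L], na.rm = TRUE)
      graphics::plot(centers, m, type = "l",
                     xlab = "window center (s)", ylab = "mean SNR(power)",
                     main = sprintf("time course, %s rate", rates[ri]))
      graphics::abline(h = 0, lty = 2)
    }
  }
  for (nm in names(cluster_tests)) {
    ct <- cluster_tests[[nm]]
    if (!nrow(ct$clusters)) next
    graphics::image(ct$times, seq_len(nrow(ct$t_map)), t(ct$t_map),
                    xlab = "time (s)", ylab = "channel",
                    main = sprintf("t map, %s (p=%.3g)", nm,
                                   ct$clusters$p[1]))
  }
  invisible(NULL)
}
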