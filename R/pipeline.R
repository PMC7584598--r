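# End-to-end orchestration of WT / HT / FM comparisons, group statistics
# (ANOVA + Tukey HSD, Kruskal-Wallis + Dunn), and report rendering.

#' Compare a metric across groups
#'
#' Omnibus test plus pairwise post-hoc comparisons, with the five-number
#' summaries used in box plots.  `anova_tukey` runs one-way ANOVA with Tukey
#' HSD; `kw_dunn` runs Kruskal-Wallis with Dunn's rank-based z tests
#' (tie-corrected) and Holm adjustment.
#'
#' @param values named list of numeric vectors, one per group (each n >= 3).
#' @param method `"kw_dunn"` or `"anova_tukey"`.
#' @param metric metric name carried into the output.
#' @return object of class `group_comparison`: list with `summaries`,
#'   `omnibus` (`statistic`, `p_value`), `pairwise` (`group1`, `group2`,
#'   `estimate`, `p_adj`).
#' @export
compare_groups <- function(values, method = c("kw_dunn", "anova_tukey"),
                           metric = "metric") {
  method <- match.arg(method)
  if (length(values) < 2L)
    stop("compare_groups: need at least 2 groups", call. = FALSE)
  ns <- vapply(values, length, integer(1))
  if (any(ns < 3L))
    stop("sample-size error: every group needs n >= 3 (got ",
         paste(ns, collapse = ","), ")", call. = FALSE)
  summaries <- do.call(rbind, lapply(names(values), function(g) {
    v <- values[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  df <- data.frame(value = unlist(values, use.names = FALSE),
                   group = factor(rep(names(values), ns),
                                  levels = names(values)))
  if (method == "anova_tukey") {
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1L]]
    omni <- list(statistic = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L])
    tk <- stats::TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group1 = vapply(nm, `[`, "", 2L),
                     group2 = vapply(nm, `[`, "", 1L),
                     estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  } else {
    kw <- stats::kruskal.test(value ~ group, data = df)
    omni <- list(statistic = unname(kw$statistic),
                 p_value = kw$p.value)
    pw <- dunn_test(df$value, df$group)
  }
  rownames(pw) <- NULL
  structure(list(metric = metric, method = method, summaries = summaries,
                 omnibus = omni, pairwise = pw),
            class = "group_comparison")
}

# Dunn's multiple-comparison z statistics on the pooled ranks, with the
# usual tie correction; two-sided p-values, Holm-adjusted.
dunn_test <- function(x, g, adjust = "holm") {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  cmb <- utils::combn(lv, 2L)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], estimate = z,
             p_adj = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s)\n", x$metric, x$method))
  print(x$summaries, row.names = FALSE)
  cat(sprintf("omnibus: statistic = %.3f, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

default_analyses <- function()
  c("angles", "asymmetry", "helix", "rg", "sasa465", "interfaces", "bonds")

#' Run the full comparison pipeline
#'
#' For each input group (e.g. WT / HT / FM assemblies) the pipeline applies
#' the analysis window and computes: inter-domain angle series with
#' per-monomer window means, G-G asymmetry, helix parameters, per-tetramer
#' radius of gyration, normalized SASA of the 465 site, the interface
#' catalog with occupancy and residue-465/BSE interactions, and (full-atom
#' inputs) interface-2 hydrogen-bond/salt-bridge counts.  Metrics present in
#' two or more groups are then compared; mixed-genotype groups are split
#' into `<group>.WT` / `<group>.MUT` statistical units.
#'
#' @param groups named list of [oligo_trajectory()] objects or structure
#'   file paths.
#' @param window a [window_spec()] applied to every group.
#' @param map a [default_domain_map()].
#' @param interface_cfg an [interface_config()].
#' @param sasa_cfg a [sasa_config()].
#' @param stats_method `"kw_dunn"` or `"anova_tukey"`.
#' @param analyses subset of
#'   `c("angles","asymmetry","helix","rg","sasa465","interfaces","bonds")`.
#' @param outdir output directory for CSV tables and the run log (`NULL`
#'   disables writing).
#' @param n_area_frames frames on which interface areas are evaluated.
#' @return result bundle (named list of data frames / comparison objects),
#'   invisibly when `outdir` is set.
#' @export
run_analysis <- function(groups, window = window_spec("all"),
                         map = default_domain_map(),
                         interface_cfg = interface_config(),
                         sasa_cfg = sasa_config(),
                         stats_method = c("kw_dunn", "anova_tukey"),
                         analyses = default_analyses(), outdir = NULL,
                         n_area_frames = 5L) {
  stats_method <- match.arg(stats_method)
  analyses <- match.arg(analyses, default_analyses(), several.ok = TRUE)
  if (!length(groups) || is.null(names(groups)))
    stop("run_analysis: 'groups' must be a named list", call. = FALSE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  say("dynhelix %s; analyses: %s; stats: %s",
      as.character(utils::packageVersion("dynhelix")),
      paste(analyses, collapse = ","), stats_method)
  res <- list(groups = list())
  units <- list(g_bse = list(), bse_stalk = list(), sasa465 = list(),
                rg = list(), helix_angle = list())
  failed <- FALSE
  for (gname in names(groups)) {
    gres <- tryCatch(
      analyze_group(groups[[gname]], gname, window, map, interface_cfg,
                    sasa_cfg, analyses, n_area_frames, say),
      error = function(e) {
        say("ERROR in group %s: %s", gname, conditionMessage(e))
        NULL
      })
    if (is.null(gres)) { failed <- TRUE; next }
    res$groups[[gname]] <- gres
    for (m in names(units)) {
      if (!is.null(gres$units[[m]])) {
        u <- gres$units[[m]]
        for (lab in names(u)) units[[m]][[lab]] <- u[[lab]]
      }
    }
  }
  res$comparisons <- list()
  for (m in names(units)) {
    ok <- units[[m]][vapply(units[[m]], length, integer(1)) >= 3L]
    if (length(ok) >= 2L) {
      res$comparisons[[m]] <- compare_groups(ok, stats_method, metric = m)
      say("compared %s across %d groups (omnibus p = %.3g)", m, length(ok),
          res$comparisons[[m]]$omnibus$p_value)
    }
  }
  res$log <- log
  if (!is.null(outdir)) {
    write_bundle(res, outdir)
    if (failed)
      warning("run_analysis: one or more groups failed; partial results kept")
    return(invisible(res))
  }
  if (failed) warning("run_analysis: one or more groups failed")
  res
}

analyze_group <- function(traj, gname, window, map, interface_cfg, sasa_cfg,
                          analyses, n_area_frames, say) {
  if (is.character(traj)) {
    if (!file.exists(traj)) stop("input file not found: ", traj, call. = FALSE)
    traj <- read_structure(traj)
  }
  traj <- tryCatch(select_window(traj, window),
                   error = function(e) { say("%s: %s (using all frames)",
                                             gname, conditionMessage(e)); traj })
  f1 <- traj$frames[[1L]]
  ids <- monomer_ids(f1, proteins_only = TRUE)
  geno <- monomer_genotypes(f1, map$mutation_site)
  mixed <- length(unique(stats::na.omit(geno[ids]))) > 1L
  label_of <- function(id) {
    if (!mixed || is.na(geno[[id]])) gname
    else paste0(gname, ".", if (geno[[id]] == "WT") "WT" else "MUT")
  }
  topo <- if (length(ids) >= 8L && length(ids) %% 4L == 0L)
    assign_topology(f1, map = map,
                    contact_cutoff = interface_cfg$contact_cutoff) else NULL
  out <- list(name = gname, n_frames = length(traj$frames),
              monomers = ids, genotype = geno, topology = topo,
              units = list())
  unit_split <- function(v) {
    labs <- vapply(names(v), label_of, "")
    lapply(split(unname(v), labs), as.numeric)
  }
  if ("angles" %in% analyses) {
    ang <- angle_series(traj, map = map)
    out$angles <- ang
    out$units$g_bse <- unit_split(window_mean_angles(ang, "g_bse"))
    out$units$bse_stalk <- unit_split(window_mean_angles(ang, "bse_stalk"))
    say("%s: angle series for %d monomers x %d frames", gname, length(ids),
        length(traj$frames))
  }
  if ("asymmetry" %in% analyses && !is.null(topo) &&
      nrow(topo$gg_partners) && !is.null(out$angles)) {
    out$asymmetry <- gg_asymmetry(out$angles, topo)
    say("%s: G-G asymmetry over %d pairs (Delta = %.2f deg)", gname,
        nrow(out$asymmetry), attr(out$asymmetry, "mean"))
  }
  if ("helix" %in% analyses && !is.null(topo)) {
    out$helix <- helix_params_series(traj, topo)
    out$units$helix_angle <- stats::setNames(
      list(out$helix$helix_angle_deg), gname)
    say("%s: helix params (mean diameter %.1f A, pitch %.1f A, angle %.2f deg)",
        gname, mean(out$helix$diameter_A), mean(out$helix$pitch_A),
        mean(out$helix$helix_angle_deg))
  }
  if ("rg" %in% analyses && !is.null(topo)) {
    out$tetramer_rg <- tetramer_rg_series(traj, topo)
    wm <- attr(out$tetramer_rg, "window_mean")
    out$units$rg <- stats::setNames(list(wm$rg_A), gname)
  }
  if ("sasa465" %in% analyses &&
      any(f1$atoms$residue_number == map$mutation_site)) {
    prof <- sasa_profile(traj, map$mutation_site, config = sasa_cfg)
    out$sasa465 <- prof
    wm <- attr(prof, "window_mean")
    out$units$sasa465 <- unit_split(
      stats::setNames(wm$normalized, wm$monomer_id))
    say("%s: residue-%d SASA profile", gname, map$mutation_site)
  }
  if ("interfaces" %in% analyses && !is.null(topo)) {
    out$interfaces <- catalog_interfaces(traj, topo, map, interface_cfg,
                                         sasa_cfg, n_area_frames)
    out$occupancy <- occupancy(out$interfaces)
    out$r465_bse <- residue465_bse_interaction(f1, topo, map, interface_cfg,
                                               sasa_cfg)
    say("%s: %d interface observations, %d types", gname,
        length(out$interfaces), length(unique(out$occupancy$itype)))
  }
  if ("bonds" %in% analyses && f1$resolution == "full_atom" &&
      length(ids) >= 2L) {
    pairs <- if (!is.null(topo)) {
      lapply(seq_len(length(topo$order) - 1L), function(i)
        topo$order[i:(i + 1L)])
    } else list(ids[1:2])
    rows <- list()
    for (f in traj$frames) {
      for (p in pairs) {
        ct <- find_contact_residues(f, p[1L], p[2L], interface_cfg)
        if (!length(ct$residues_a)) next
        rows[[length(rows) + 1L]] <- data.frame(
          monomer_a = p[1L], monomer_b = p[2L], frame_index = f$frame_index,
          n_hbonds = count_hbonds(f, p, restrict_to = ct),
          n_saltbridges = count_salt_bridges(f, p, restrict_to = ct))
      }
    }
    out$bonds <- if (length(rows)) do.call(rbind, rows)
    say("%s: bond counts on %d pair-frames", gname, length(rows))
  }
  out
}

write_bundle <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, nm) utils::write.csv(df, file.path(outdir, nm),
                                            row.names = FALSE)
  pull <- function(field, extra = NULL) {
    do.call(rbind, lapply(names(res$groups), function(g) {
      x <- res$groups[[g]][[field]]
      if (is.null(x)) return(NULL)
      cbind(data.frame(group = g), as.data.frame(x))
    }))
  }
  for (f in c("angles", "helix", "tetramer_rg", "sasa465", "occupancy")) {
    df <- pull(f)
    if (!is.null(df)) wcsv(df, paste0(f, ".csv"))
  }
  asym <- pull("asymmetry")
  if (!is.null(asym)) wcsv(asym, "asymmetry.csv")
  insts <- do.call(rbind, lapply(names(res$groups), function(g) {
    x <- res$groups[[g]]$interfaces
    if (!length(x)) return(NULL)
    do.call(rbind, lapply(x, function(i) data.frame(
      group = g, monomer_a = i$pair[1L], monomer_b = i$pair[2L],
      itype = i$itype, frame_index = i$frame_index, area_A2 = i$area_A2,
      n_residues = length(i$residues_a) + length(i$residues_b))))
  }))
  if (!is.null(insts)) wcsv(insts, "interfaces.csv")
  bonds <- pull("bonds")
  if (!is.null(bonds)) wcsv(bonds, "bonds.csv")
  if (length(res$comparisons)) {
    cmp <- do.call(rbind, lapply(res$comparisons, function(x)
      cbind(data.frame(metric = x$metric, method = x$method,
                       omnibus_p = x$omnibus$p_value), x$pairwise)))
    wcsv(cmp, "comparisons.csv")
  }
  writeLines(res$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Render summary figures from a result bundle
#'
#' Violin+box plots of the angle distributions, occupancy heatmaps and
#' helix-parameter traces.  Rendering is best-effort: figures are optional
#' outputs and failures are reported as messages, never errors.
#'
#' @param bundle result of [run_analysis()].
#' @param outdir output directory.
#' @return character vector of files written.
#' @export
render_reports <- function(bundle, outdir = ".") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_fig <- function(p, nm, w = 7, h = 5) {
    path <- file.path(outdir, nm)
    ok <- tryCatch({
      ggplot2::ggsave(path, p, width = w, height = h, dpi = 110)
      TRUE
    }, error = function(e) {
      message("figure skipped (", nm, "): ", conditionMessage(e)); FALSE
    })
    if (ok) written <<- c(written, path)
  }
  ang <- do.call(rbind, lapply(names(bundle$groups), function(g) {
    a <- bundle$groups[[g]]$angles
    if (is.null(a)) return(NULL)
    cbind(data.frame(group = g), a)
  }))
  if (!is.null(ang) && nrow(ang)) {
    p <- ggplot2::ggplot(ang, ggplot2::aes(x = .data$group, y = .data$degrees)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
      ggplot2::facet_wrap(~angle_name, scales = "free_y") +
      ggplot2::labs(y = "angle (deg)", x = NULL)
    save_fig(p, "angles.png")
  } else message("figure skipped (angles.png): no angle series")
  occ <- do.call(rbind, lapply(names(bundle$groups), function(g) {
    o <- bundle$groups[[g]]$occupancy
    if (is.null(o) || !nrow(o)) return(NULL)
    cbind(data.frame(group = g), o)
  }))
  if (!is.null(occ) && nrow(occ)) {
    p <- ggplot2::ggplot(occ, ggplot2::aes(x = .data$group,
                                           y = factor(.data$residue_number),
                                           fill = .data$fraction)) +
      ggplot2::geom_tile() + ggplot2::facet_wrap(~itype, scales = "free_y") +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(y = "residue", fill = "occupancy")
    save_fig(p, "occupancy.png", w = 8, h = 9)
  } else message("figure skipped (occupancy.png): no occupancy table")
  hx <- do.call(rbind, lapply(names(bundle$groups), function(g) {
    h <- bundle$groups[[g]]$helix
    if (is.null(h)) return(NULL)
    cbind(data.frame(group = g), h)
  }))
  if (!is.null(hx) && nrow(hx)) {
    p <- ggplot2::ggplot(hx, ggplot2::aes(x = .data$frame_index,
                                          y = .data$helix_angle_deg,
                                          colour = .data$group)) +
      ggplot2::geom_line() + ggplot2::labs(y = "helix angle (deg)")
    save_fig(p, "helix_angle.png")
  } else message("figure skipped (helix_angle.png): no helix series")
  written
}
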