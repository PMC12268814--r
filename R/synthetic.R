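#' Kinetic profile of one target/primer-set combination
#'
#' Mean five-parameter sigmoid values for the curves this primer set
#' produces on this target, with per-parameter coefficients of variation
#' (lognormal jitter preserves positivity) and a concentration law: `Cs`
#' increases by `ct_shift_per_log10` cycles per 10-fold template dilution,
#' while the shape parameters (`Sc`, `As`) are concentration-independent by
#' construction — the mechanism behind the concentration robustness of the
#' shape-derived features. The default shift of 3.3 cycles per decade is
#' that of a fully efficient PCR (log2(10)).
#'
#' @param target target label.
#' @param primer_set primer-set id.
#' @param Fm,Fb,Sc,Cs,As mean sigmoid parameters (see [sigmoid_params()]).
#' @param cv named numeric vector of coefficients of variation for any of
#'   the five parameters (missing entries default to the values shown).
#' @param ct_shift_per_log10 Cs increase (cycles) per 10-fold dilution.
#' @return One-row data frame; rows are stacked into a profile table.
#' @export
kinetic_profile <- function(target, primer_set, Fm = 1000, Fb = 50,
                            Sc = 0.8, Cs = 25, As = 1.5,
                            cv = c(Fm = 0.05, Fb = 0.05, Sc = 0.03,
                                   Cs = 0.02, As = 0.05),
                            ct_shift_per_log10 = 3.3) {
  cv0 <- c(Fm = 0.05, Fb = 0.05, Sc = 0.03, Cs = 0.02, As = 0.05)
  cv0[names(cv)] <- cv
  validate_sigmoid_params(c(Fm = Fm, Fb = Fb, Sc = Sc, Cs = Cs, As = As))
  if (any(cv0 < 0)) stop("coefficients of variation must be >= 0")
  data.frame(target = target, primer_set = primer_set,
             Fm = Fm, Fb = Fb, Sc = Sc, Cs = Cs, As = As,
             cv_Fm = cv0[["Fm"]], cv_Fb = cv0[["Fb"]], cv_Sc = cv0[["Sc"]],
             cv_Cs = cv0[["Cs"]], cv_As = cv0[["As"]],
             ct_shift_per_log10 = ct_shift_per_log10,
             stringsAsFactors = FALSE)
}

#' Scenario describing a synthetic amplification-curve dataset
#'
#' Bundles kinetic profiles with the experimental design (concentrations,
#' replicates, cycle grid), the noise model, the multiplex attenuation
#' model and contamination rates. With a fixed `seed` every generator is
#' fully deterministic.
#'
#' @param profiles data frame of stacked [kinetic_profile()] rows.
#' @param concentrations template concentrations (copies per reaction).
#' @param n_curves replicate curves per (target, primer set, concentration).
#' @param cycles cycle grid; default 45 unit-spaced cycles.
#' @param noise_sigma_rel additive Gaussian fluorescence noise SD as a
#'   fraction of each curve's `Fm`; default 0.005.
#' @param alpha_Fm,beta_Sc multiplex attenuation factors applied to `Fm`
#'   and `Sc` (reaction efficiency drops when primers compete); default
#'   0.8 each.
#' @param attenuation_jitter lognormal SD of the per-curve attenuation
#'   jitter; default 0.02.
#' @param contamination named fractions (of the clean curve count) of
#'   `flat`, `low_gain` and `low_efficiency` contaminant curves.
#' @param seed integer seed.
#' @return A list of class `plex_scenario`.
#' @export
plex_scenario <- function(profiles,
                          concentrations = c(1e2, 1e3, 1e4, 1e5),
                          n_curves = 6, cycles = 1:45,
                          noise_sigma_rel = 0.005,
                          alpha_Fm = 0.8, beta_Sc = 0.8,
                          attenuation_jitter = 0.02,
                          contamination = c(flat = 0, low_gain = 0,
                                            low_efficiency = 0),
                          seed = 1) {
  cont <- c(flat = 0, low_gain = 0, low_efficiency = 0)
  cont[names(contamination)] <- contamination
  if (any(cont < 0 | cont > 1))
    stop("contamination fractions must lie in [0, 1]")
  if (!(alpha_Fm > 0 && alpha_Fm <= 1 && beta_Sc > 0 && beta_Sc <= 1))
    stop("attenuation factors must lie in (0, 1]")
  structure(list(profiles = profiles, concentrations = concentrations,
                 ref_concentration = max(concentrations),
                 n_curves = n_curves, cycles = cycles,
                 noise_sigma_rel = noise_sigma_rel,
                 alpha_Fm = alpha_Fm, beta_Sc = beta_Sc,
                 attenuation_jitter = attenuation_jitter,
                 contamination = cont, seed = as.integer(seed)),
            class = "plex_scenario")
}

# lognormal jitter with mean preserved: E[x * exp(N(-s^2/2, s))] = x
.jitter_param <- function(x, cv, n) {
  if (cv <= 0) return(rep(x, n))
  s <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(n, -s^2 / 2, s))
}

.draw_params <- function(prof, conc, ref_conc, n) {
  shift <- prof$ct_shift_per_log10 * log10(ref_conc / conc)
  data.frame(
    Fm = .jitter_param(prof$Fm, prof$cv_Fm, n),
    Fb = .jitter_param(prof$Fb, prof$cv_Fb, n),
    Sc = .jitter_param(prof$Sc, prof$cv_Sc, n),
    Cs = .jitter_param(prof$Cs + shift, prof$cv_Cs, n),
    As = .jitter_param(prof$As, prof$cv_As, n))
}

.synth_block <- function(scenario, prof, conc, n, id_prefix, reaction_type,
                         alpha_Fm = 1, beta_Sc = 1, jitter = 0) {
  par <- .draw_params(prof, conc, scenario$ref_concentration, n)
  if (alpha_Fm < 1 || beta_Sc < 1 || jitter > 0) {
    par$Fm <- par$Fm * alpha_Fm * exp(stats::rnorm(n, 0, jitter))
    par$Sc <- par$Sc * beta_Sc * exp(stats::rnorm(n, 0, jitter))
  }
  tt <- scenario$cycles
  curves <- vector("list", n)
  ids <- sprintf("%s_%02d", id_prefix, seq_len(n))
  for (i in seq_len(n)) {
    p <- unlist(par[i, ])
    f <- eval_sigmoid(p, tt) +
      stats::rnorm(length(tt), 0, scenario$noise_sigma_rel * p[["Fm"]])
    curves[[i]] <- list(cycles = tt, fluorescence = f)
  }
  names(curves) <- ids
  meta <- data.frame(curve_id = ids, target = prof$target,
                     primer_set = prof$primer_set, concentration = conc,
                     panel_id = NA_character_, reaction_type = reaction_type,
                     contaminant = NA_character_, stringsAsFactors = FALSE)
  list(curves = curves, metadata = meta,
       params = cbind(data.frame(curve_id = ids, stringsAsFactors = FALSE),
                      par))
}

.bind_blocks <- function(blocks) {
  list(curves = do.call(c, lapply(blocks, `[[`, "curves")),
       metadata = do.call(rbind, lapply(blocks, `[[`, "metadata")),
       params = do.call(rbind, lapply(blocks, `[[`, "params")))
}

#' Generate a singleplex amplification-curve dataset
#'
#' For every (target, primer set, concentration) cell, draws `n_curves`
#' parameter vectors around the profile means (lognormal jitter at the
#' stated CVs), shifts `Cs` by the concentration law, synthesises the
#' fluorescence trace on the cycle grid and adds Gaussian noise. The true
#' injected parameters are returned alongside for round-trip testing.
#'
#' @param scenario a [plex_scenario()].
#' @return A list with `curves` (named list of `list(cycles,
#'   fluorescence)`), `metadata` (data frame: `curve_id`, `target`,
#'   `primer_set`, `concentration`, `panel_id`, `reaction_type`,
#'   `contaminant`) and `params` (true per-curve parameters).
#' @export
generate_singleplex <- function(scenario) {
  stopifnot(inherits(scenario, "plex_scenario"))
  set.seed(scenario$seed)
  blocks <- list()
  for (r in seq_len(nrow(scenario$profiles))) {
    prof <- scenario$profiles[r, ]
    for (conc in scenario$concentrations) {
      pre <- sprintf("sp_%s_%s_c%g", prof$target, prof$primer_set,
                     log10(conc))
      blocks[[length(blocks) + 1]] <-
        .synth_block(scenario, prof, conc, scenario$n_curves, pre,
                     "singleplex")
    }
  }
  .bind_blocks(blocks)
}

#' Generate a multiplex dataset for one candidate primer mix
#'
#' As [generate_singleplex()] but restricted to the candidate's assigned
#' primer sets and with the multiplex efficiency attenuation applied:
#' `Fm <- alpha_Fm * Fm` and `Sc <- beta_Sc * Sc`, each with a small
#' per-curve lognormal jitter. The near-linear map from singleplex to
#' multiplex parameters yields the strong linear feature correlation the
#' framework relies on.
#'
#' @inheritParams generate_singleplex
#' @param candidate named character vector mapping target to primer-set id.
#' @return Same structure as [generate_singleplex()], with
#'   `reaction_type = "multiplex"`.
#' @export
generate_multiplex <- function(scenario, candidate) {
  stopifnot(inherits(scenario, "plex_scenario"))
  candidate <- unlist(candidate)
  candidate <- candidate[setdiff(names(candidate), "mix_id")]
  set.seed(scenario$seed + 1L)
  blocks <- list()
  for (tg in names(candidate)) {
    prof <- scenario$profiles[scenario$profiles$target == tg &
                              scenario$profiles$primer_set == candidate[[tg]], ]
    if (nrow(prof) != 1)
      stop("scenario has no profile for target/primer set ",
           tg, "/", candidate[[tg]])
    for (conc in scenario$concentrations) {
      pre <- sprintf("mp_%s_%s_c%g", prof$target, prof$primer_set,
                     log10(conc))
      blocks[[length(blocks) + 1]] <-
        .synth_block(scenario, prof, conc, scenario$n_curves, pre,
                     "multiplex", alpha_Fm = scenario$alpha_Fm,
                     beta_Sc = scenario$beta_Sc,
                     jitter = scenario$attenuation_jitter)
    }
  }
  .bind_blocks(blocks)
}

#' Generate contaminant curves (NTC/flat, low-gain, low-efficiency)
#'
#' Emulates the failure modes a preprocessing filter must remove: flat
#' no-template traces (baseline plus noise), low-gain curves (sigmoid with
#' gain below the filter gate) and low-efficiency curves (`Sc = 0.05`).
#' Counts are the contamination fractions times the clean curve count of
#' the scenario; each curve carries its ground-truth type in the
#' `contaminant` metadata column.
#'
#' @inheritParams generate_singleplex
#' @return Same structure as [generate_singleplex()] (empty data frames
#'   when all fractions are zero).
#' @export
generate_contaminants <- function(scenario) {
  stopifnot(inherits(scenario, "plex_scenario"))
  set.seed(scenario$seed + 2L)
  n_clean <- nrow(scenario$profiles) * length(scenario$concentrations) *
    scenario$n_curves
  tt <- scenario$cycles
  fb <- stats::median(scenario$profiles$Fb)
  fm <- stats::median(scenario$profiles$Fm)
  curves <- list(); meta <- list()
  add <- function(id, f, type) {
    curves[[id]] <<- list(cycles = tt, fluorescence = f)
    meta[[id]] <<- data.frame(curve_id = id, target = NA_character_,
                              primer_set = NA_character_,
                              concentration = NA_real_,
                              panel_id = NA_character_,
                              reaction_type = "ntc", contaminant = type,
                              stringsAsFactors = FALSE)
  }
  n_flat <- round(scenario$contamination[["flat"]] * n_clean)
  for (i in seq_len(n_flat))
    add(sprintf("ntc_flat_%03d", i),
        fb + stats::rnorm(length(tt), 0, 0.002 * fm), "flat")
  n_lg <- round(scenario$contamination[["low_gain"]] * n_clean)
  for (i in seq_len(n_lg)) {
    p <- c(Fm = 0.03 * fb, Fb = fb, Sc = 0.6,
           Cs = stats::median(tt), As = 1)
    add(sprintf("ntc_lowgain_%03d", i),
        eval_sigmoid(p, tt) + stats::rnorm(length(tt), 0, 0.001 * fb),
        "low_gain")
  }
  n_le <- round(scenario$contamination[["low_efficiency"]] * n_clean)
  for (i in seq_len(n_le)) {
    p <- c(Fm = fm, Fb = fb, Sc = 0.05, Cs = max(tt), As = 1)
    add(sprintf("ntc_loweff_%03d", i),
        eval_sigmoid(p, tt) + stats::rnorm(length(tt), 0, 0.002 * fm),
        "low_efficiency")
  }
  if (!length(curves))
    return(list(curves = list(),
                metadata = data.frame(curve_id = character(0)),
                params = NULL))
  list(curves = curves, metadata = do.call(rbind, unname(meta)),
       params = NULL)
}

#' Preset scenario: a 7-plex panel with two primer sets per target
#'
#' Seven targets, two candidate primer sets each (128 candidate mixes),
#' four template concentrations spanning 10^2 to 10^5 copies per reaction.
#' Targets differ mainly in slope coefficient and asymmetry so that the
#' shape-derived features separate them; the two sets of one target differ
#' slightly in timing and slope, as alternative primer pairs do.
#'
#' @param seed integer seed.
#' @param n_curves replicates per (target, primer set, concentration);
#'   default 6.
#' @param ... passed on to [plex_scenario()].
#' @return A [plex_scenario()].
#' @export
scenario_preset_7plex <- function(seed = 1, n_curves = 6, ...) {
  sc <- c(0.50, 0.60, 0.70, 0.80, 0.90, 1.00, 1.10)
  as_ <- c(0.8, 1.0, 1.3, 1.6, 2.0, 2.4, 2.9)
  fm <- c(950, 1000, 1050, 900, 1000, 1100, 980)
  cs <- c(24, 26, 25, 27, 23, 26, 25)
  profs <- list()
  for (i in 1:7) {
    tg <- sprintf("T%d", i)
    profs[[length(profs) + 1]] <-
      kinetic_profile(tg, paste0(tg, "a"), Fm = fm[i], Fb = 50,
                      Sc = sc[i], Cs = cs[i], As = as_[i])
    profs[[length(profs) + 1]] <-
      kinetic_profile(tg, paste0(tg, "b"), Fm = fm[i] * 0.95, Fb = 50,
                      Sc = sc[i] * 1.04, Cs = cs[i] + 1, As = as_[i] * 1.05)
  }
  plex_scenario(do.call(rbind, profs), n_curves = n_curves, seed = seed, ...)
}

#' Demonstration 3-plex where median and clustering distances disagree
#'
#' Builds a labelled singleplex feature table for three targets A, B, C.
#' B and C each have one primer set; A has four. Sets `a1`, `a3`, `a4`
#' produce tight clusters whose slope coefficient sits close to B's, while
#' set `a2` produces a cluster whose `Sc` median is far from both B and C
#' (attractive to a median-based single-feature score) but whose
#' shape-feature variance is so large that it overlaps both other targets
#' (penalised by the clustering-based silhouette score). The single-feature
#' median strategy therefore ranks the `a2` candidate near the top while
#' the clustering strategy ranks it near the bottom.
#'
#' @param seed integer seed.
#' @param n_per_cluster points per (target, primer set) cluster.
#' @return A list with `features` (data frame: `target`, `primer_set`,
#'   `Sc`, `slope_ms`, `curv_p1`, `neg_curv_p2`) and `candidates` (from
#'   [enumerate_candidates()]; the pathological candidate assigns `a2`).
#' @export
simulate_overlap_panel <- function(seed = 1, n_per_cluster = 30) {
  set.seed(seed)
  mk <- function(target, primer_set, mu, sd) {
    data.frame(target = target, primer_set = primer_set,
               Sc = stats::rnorm(n_per_cluster, mu[1], sd[1]),
               slope_ms = stats::rnorm(n_per_cluster, mu[2], sd[2]),
               curv_p1 = stats::rnorm(n_per_cluster, mu[3], sd[3]),
               neg_curv_p2 = stats::rnorm(n_per_cluster, mu[4], sd[4]),
               stringsAsFactors = FALSE)
  }
  tight <- c(0.01, 0.5, 0.1, 0.1)
  features <- rbind(
    mk("B", "b1", c(0.50, 100, 10.0, 8.0), tight),
    mk("C", "c1", c(0.90, 140, 14.0, 11.0), tight),
    mk("A", "a1", c(0.52, 118, 11.8, 9.3), tight),
    mk("A", "a2", c(1.60, 120, 12.0, 9.5), c(0.02, 25, 2.5, 2.0)),
    mk("A", "a3", c(0.55, 122, 12.2, 9.7), tight),
    mk("A", "a4", c(0.58, 126, 12.6, 10.1), tight))
  candidates <- enumerate_candidates(
    list(A = c("a1", "a2", "a3", "a4"), B = "b1", C = "c1"))
  list(features = features, candidates = candidates)
}
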