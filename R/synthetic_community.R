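#' Configuration for the synthetic community generator
#'
#' Describes a two-habitat amplicon study design with planted, recorded
#' ground truth. Defaults emulate the motivating design: six drainage and six
#' soil samples; three drainage generalists (the first one dominating the
#' drainage core at an expected 48.6% of core sequences) and no drainage
#' specialists; one soil generalist and one soil specialist; a planted core
#' background present everywhere but below the 2% classification threshold;
#' and OTU-chemistry monotone associations at the strengths reported for the
#' copper-mine habitat (copper 0.77, nickel 0.84, sulfur 0.88 for the
#' dominant drainage generalist; sulfur 0.82 for the soil generalist).
#'
#' Planted abundance targets must clear the classification threshold by the
#' stated `margin` (default 50%): generalists and specialists sit at or above
#' `threshold * (1 + margin)` and all background (planted or random) below
#' `threshold * (1 - margin)`, so recovery under multinomial noise is
#' well-posed. Non-planted background OTUs occupy between half and all-but-one
#' of an environment's samples, which keeps the planted core and specialist
#' ground truth unambiguous.
#'
#' @param environments character vector of habitat labels.
#' @param n_samples samples per environment (scalar or named vector).
#' @param n_otus total number of OTUs (planted + background).
#' @param depth_mean,depth_cv mean sequencing depth per sample and its
#'   coefficient of variation (`depth_cv = 0` gives fixed depths).
#' @param n_generalists,n_specialists,n_core_background planted counts per
#'   environment (scalar or named vector).
#' @param specialist_occupancy 1 or 2 samples per specialist.
#' @param generalist_ra,specialist_ra,core_background_ra target relative
#'   abundances of planted OTUs (specialists: within their occupied samples).
#' @param background_sdlog log-normal sd of background abundance draws.
#' @param threshold,margin classification threshold and the relative margin
#'   planted abundances must keep from it.
#' @param dominant_core_share named numeric vector: for each named
#'   environment, the expected share (fraction) of core sequences taken by
#'   the first generalist, whose abundance is solved accordingly; `NULL`
#'   disables.
#' @param overdispersion Dirichlet overdispersion of per-sample compositions
#'   (0 = plain multinomial).
#' @param associations data.frame with columns `environment`, `role`
#'   (`"generalist"`, `"specialist"` or `"core_background"`), `index`
#'   (within-role, per environment), `parameter`, `rho` (target Spearman);
#'   at most one association per (environment, parameter).
#' @param chemistry_parameters parameter names to generate.
#' @param seed default seed used by [generate_community] when none is given.
#' @return validated list of class `community_config`.
#' @export
community_config <- function(environments = c("drainage", "soil"),
                             n_samples = 6,
                             n_otus = 200,
                             depth_mean = 10000,
                             depth_cv = 0.1,
                             n_generalists = c(drainage = 3, soil = 1),
                             n_specialists = c(drainage = 0, soil = 1),
                             n_core_background = c(drainage = 20, soil = 10),
                             specialist_occupancy = 2,
                             generalist_ra = 0.03,
                             specialist_ra = 0.10,
                             core_background_ra = 0.005,
                             background_sdlog = 1,
                             threshold = 0.02,
                             margin = 0.5,
                             dominant_core_share = c(drainage = 0.486),
                             overdispersion = 0,
                             associations = NULL,
                             chemistry_parameters = canonical_chemistry_parameters(),
                             seed = NULL) {
  per_env <- function(x, what) {
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(x, length(environments)), environments))
    if (!all(environments %in% names(x)))
      .stopf("%s must be a scalar or named for every environment", what)
    x[environments]
  }
  cfg <- list(
    environments = environments,
    n_samples = per_env(n_samples, "n_samples"),
    n_otus = n_otus,
    depth_mean = depth_mean, depth_cv = depth_cv,
    n_generalists = per_env(n_generalists, "n_generalists"),
    n_specialists = per_env(n_specialists, "n_specialists"),
    n_core_background = per_env(n_core_background, "n_core_background"),
    specialist_occupancy = specialist_occupancy,
    generalist_ra = generalist_ra, specialist_ra = specialist_ra,
    core_background_ra = core_background_ra,
    background_sdlog = background_sdlog,
    threshold = threshold, margin = margin,
    dominant_core_share = dominant_core_share,
    overdispersion = overdispersion,
    associations = if (is.null(associations)) .default_associations(environments)
                   else associations,
    chemistry_parameters = chemistry_parameters,
    seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "community_config")
}

.default_associations <- function(environments) {
  rows <- list()
  if ("drainage" %in% environments)
    rows$dr <- data.frame(environment = "drainage", role = "generalist",
                          index = 1L,
                          parameter = c("copper", "nickel", "sulfur"),
                          rho = c(0.77, 0.84, 0.88), stringsAsFactors = FALSE)
  if ("soil" %in% environments)
    rows$so <- data.frame(environment = "soil", role = "generalist",
                          index = 1L, parameter = "sulfur", rho = 0.82,
                          stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(environment = character(), role = character(),
                      index = integer(), parameter = character(),
                      rho = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, unname(rows))
}

.gen_ras <- function(cfg, env) {
  ng <- cfg$n_generalists[[env]]
  if (ng == 0) return(numeric(0))
  ras <- rep(cfg$generalist_ra, ng)
  s <- cfg$dominant_core_share
  if (!is.null(s) && env %in% names(s) && !is.na(s[[env]])) {
    others <- (ng - 1) * cfg$generalist_ra +
      cfg$n_core_background[[env]] * cfg$core_background_ra
    if (others <= 0)
      .stopf("dominant_core_share needs at least one other core member in '%s'", env)
    ras[1] <- s[[env]] / (1 - s[[env]]) * others
  }
  ras
}

.validate_config <- function(cfg) {
  if (any(cfg$n_samples < 3)) .stopf("each environment needs >= 3 samples")
  if (!cfg$specialist_occupancy %in% c(1L, 2L))
    .stopf("specialist_occupancy must be 1 or 2")
  for (v in c("generalist_ra", "specialist_ra", "core_background_ra"))
    if (cfg[[v]] <= 0 || cfg[[v]] >= 1) .stopf("%s must be in (0,1)", v)
  if (cfg$threshold <= 0 || cfg$threshold >= 1) .stopf("threshold must be in (0,1)")
  lo <- cfg$threshold * (1 + cfg$margin)
  hi <- cfg$threshold * (1 - cfg$margin)
  if (cfg$generalist_ra < lo)
    .stopf("generalist_ra (%g) below threshold margin %g", cfg$generalist_ra, lo)
  if (cfg$specialist_ra < lo)
    .stopf("specialist_ra (%g) below threshold margin %g", cfg$specialist_ra, lo)
  if (cfg$core_background_ra > hi)
    .stopf("core_background_ra (%g) above background margin %g",
           cfg$core_background_ra, hi)
  n_planted <- sum(cfg$n_generalists + cfg$n_specialists + cfg$n_core_background)
  if (n_planted + 5 > cfg$n_otus)
    .stopf("n_otus (%d) too small for %d planted OTUs plus background",
           cfg$n_otus, n_planted)
  for (env in cfg$environments) {
    ras <- .gen_ras(cfg, env)
    if (length(ras) && any(ras < lo))
      .stopf("solved generalist abundance below margin in '%s'", env)
    planted_mass <- sum(ras) +
      cfg$n_core_background[[env]] * cfg$core_background_ra +
      min(cfg$n_specialists[[env]], 1) * cfg$specialist_ra * cfg$n_specialists[[env]]
    if (planted_mass >= 0.9)
      .stopf("planted expected abundances sum to %.2f in '%s'; infeasible",
             planted_mass, env)
  }
  a <- cfg$associations
  if (nrow(a)) {
    need <- c("environment", "role", "index", "parameter", "rho")
    if (!all(need %in% names(a))) .stopf("associations needs columns: %s",
                                         paste(need, collapse = ", "))
    if (anyDuplicated(a[, c("environment", "parameter")]))
      .stopf("at most one association per (environment, parameter)")
    if (any(abs(a$rho) >= 1)) .stopf("association rho must be in (-1, 1)")
    if (!all(a$parameter %in% cfg$chemistry_parameters))
      .stopf("association parameter(s) not in chemistry_parameters")
    if (!all(a$environment %in% cfg$environments))
      .stopf("association environment(s) not in config")
  }
  invisible(cfg)
}

.sample_ids <- function(cfg) {
  abbr <- toupper(substr(cfg$environments, 1, 1))
  if (anyDuplicated(abbr)) abbr <- paste0(cfg$environments, "_")
  unlist(lapply(seq_along(cfg$environments), function(i) {
    paste0(abbr[i], seq_len(cfg$n_samples[[cfg$environments[i]]]))
  }), use.names = FALSE)
}

# Build the expected relative-abundance matrix and the planted plan.
# Uses the current RNG stream.
.build_expectations <- function(cfg) {
  envs <- cfg$environments
  sample_env <- rep(envs, cfg$n_samples[envs])
  sample_ids <- .sample_ids(cfg)
  names(sample_env) <- sample_ids

  plan <- list()
  otu_counter <- 0
  next_ids <- function(k, prefix) {
    ids <- sprintf("OTU_%04d", otu_counter + seq_len(k))
    otu_counter <<- otu_counter + k
    ids
  }
  for (env in envs) {
    plan[[env]] <- list(
      generalists = next_ids(cfg$n_generalists[[env]]),
      specialists = next_ids(cfg$n_specialists[[env]]),
      core_background = next_ids(cfg$n_core_background[[env]]))
  }
  n_bg <- cfg$n_otus - otu_counter
  bg_ids <- next_ids(n_bg)
  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))

  E <- matrix(0, cfg$n_otus, length(sample_ids),
              dimnames = list(otu_ids, sample_ids))
  spec_sites <- list()
  cap <- cfg$threshold * (1 - cfg$margin)

  for (env in envs) {
    cols <- sample_ids[sample_env == env]
    n <- length(cols)
    pl <- plan[[env]]
    gen_ras <- .gen_ras(cfg, env)
    if (length(pl$generalists))
      E[pl$generalists, cols] <- matrix(gen_ras, length(gen_ras), n)
    for (sid in pl$specialists) {
      sites <- sample(cols, cfg$specialist_occupancy)
      E[sid, sites] <- cfg$specialist_ra
      spec_sites[[sid]] <- sites
    }
    if (length(pl$core_background))
      E[pl$core_background, cols] <- cfg$core_background_ra

    # background: occupancy between half and all-but-one samples, log-normal
    # weights, column-normalized to the remaining mass, then iteratively
    # capped below the background margin
    planted_mass <- colSums(E[setdiff(otu_ids, bg_ids), cols, drop = FALSE])
    remaining <- 1 - planted_mass
    lo <- ceiling(n / 2); hi <- n - 1
    occ <- if (lo >= hi) rep(lo, n_bg) else sample(lo:hi, n_bg, replace = TRUE)
    target_w <- mean(remaining) / (n_bg * mean(occ) / n)
    w <- pmax(stats::rlnorm(n_bg, log(target_w) - cfg$background_sdlog^2 / 2,
                            cfg$background_sdlog), 1e-4 * target_w)
    B <- matrix(0, n_bg, n, dimnames = list(bg_ids, cols))
    for (b in seq_len(n_bg)) B[b, sample(n, occ[b])] <- w[b]
    renorm <- function(B) sweep(B, 2, remaining / colSums(B), "*")
    B <- renorm(B)
    for (it in seq_len(100)) {
      occ_mean <- rowSums(B) / pmax(rowSums(B > 0), 1)
      over <- occ_mean > 0.95 * cap
      if (!any(over)) break
      B[over, ] <- B[over, , drop = FALSE] * (0.9 * cap / occ_mean[over])
      B <- renorm(B)
    }
    occ_mean <- rowSums(B) / pmax(rowSums(B > 0), 1)
    if (any(occ_mean > cap))
      .stopf("infeasible config: background abundance cannot stay below the margin in '%s'", env)
    E[bg_ids, cols] <- B
  }
  stopifnot(all(abs(colSums(E) - 1) < 1e-9))
  list(E = E, plan = plan, bg_ids = bg_ids, sample_env = sample_env,
       spec_sites = spec_sites)
}

.make_taxonomy <- function(cfg, plan, bg_ids) {
  otu_ids <- character(0); genus <- character(0)
  multi_dom <- sum(!is.na(cfg$dominant_core_share)) > 1
  for (env in cfg$environments) {
    pl <- plan[[env]]
    g <- pl$generalists
    if (length(g)) {
      gn <- paste0("Generalist_", env, "_", seq_along(g))
      if (!is.null(cfg$dominant_core_share) &&
          env %in% names(cfg$dominant_core_share))
        gn[1] <- if (multi_dom) paste0("CoreDominant_", env) else "CoreDominant"
      otu_ids <- c(otu_ids, g); genus <- c(genus, gn)
    }
    if (length(pl$specialists)) {
      otu_ids <- c(otu_ids, pl$specialists)
      genus <- c(genus, paste0("Specialist_", env, "_", seq_along(pl$specialists)))
    }
    if (length(pl$core_background)) {
      otu_ids <- c(otu_ids, pl$core_background)
      genus <- c(genus, paste0("CoreMinor_", env, "_",
                               seq_along(pl$core_background)))
    }
  }
  if (length(bg_ids)) {
    bgen <- paste0("Background_", rep_len(1:10, length(bg_ids)))
    bgen[seq_along(bg_ids) %% 5 == 0] <- NA_character_  # some unclassified
    otu_ids <- c(otu_ids, bg_ids); genus <- c(genus, bgen)
  }
  tax <- data.frame(otu_id = otu_ids, domain = "Bacteria",
                    phylum = NA_character_, class = NA_character_,
                    order = NA_character_, family = NA_character_,
                    genus = genus, stringsAsFactors = FALSE)
  tax[match(sort(otu_ids), tax$otu_id), ]
}

.draw_counts <- function(E, cfg) {
  n_s <- ncol(E)
  depths <- if (cfg$depth_cv > 0) {
    pmax(50L, as.integer(round(stats::rnorm(n_s, cfg$depth_mean,
                                            cfg$depth_cv * cfg$depth_mean))))
  } else rep(as.integer(cfg$depth_mean), n_s)
  counts <- matrix(0L, nrow(E), n_s, dimnames = dimnames(E))
  for (s in seq_len(n_s)) {
    p <- E[, s]
    if (cfg$overdispersion > 0) {
      g <- stats::rgamma(length(p), shape = p / cfg$overdispersion)
      p <- if (sum(g) > 0) g / sum(g) else p
    }
    counts[, s] <- as.integer(stats::rmultinom(1, depths[s], p))
  }
  counts
}

# Chemistry with Spearman-calibrated associations. For a target Spearman
# rho_s, the parameter's latent value within the associated environment is
# w * s + sqrt(1 - w^2) * noise, where s are the standardized normal scores
# of the OTU's realized abundance ranks and w = 2 sin(pi * rho_s / 6) is the
# bivariate-normal Pearson weight whose Spearman correlation is rho_s. A
# strictly increasing per-parameter transform then maps the latent scale to
# plausible units; Spearman correlations are invariant to it.
.chem_scales <- function() {
  list(pH = c(type = 0, loc = 7, spread = 0.5),
       organic_matter = c(type = 1, loc = 4, spread = 0.5),
       calcium = c(type = 1, loc = 2000, spread = 0.8),
       copper = c(type = 1, loc = 800, spread = 0.9),
       sulfur = c(type = 1, loc = 1500, spread = 0.9),
       iron = c(type = 1, loc = 30000, spread = 0.6))
}

.make_chemistry <- function(cfg, relab, sample_env, plan) {
  sample_ids <- colnames(relab)
  params <- cfg$chemistry_parameters
  Z <- matrix(stats::rnorm(length(sample_ids) * length(params)),
              length(sample_ids), length(params),
              dimnames = list(sample_ids, params))
  a <- cfg$associations
  resolved <- character(nrow(a))
  if (nrow(a)) for (i in seq_len(nrow(a))) {
    pl <- plan[[a$environment[i]]]
    pool <- switch(a$role[i], generalist = pl$generalists,
                   specialist = pl$specialists,
                   core_background = pl$core_background,
                   .stopf("unknown association role '%s'", a$role[i]))
    if (a$index[i] > length(pool))
      .stopf("association index %d exceeds %s count in '%s'",
             a$index[i], a$role[i], a$environment[i])
    otu <- pool[a$index[i]]
    resolved[i] <- otu
    cols <- sample_ids[sample_env == a$environment[i]]
    x <- relab[otu, cols]
    r <- rank(x)
    s <- stats::qnorm((r - 0.5) / length(r))
    s <- s / stats::sd(s)
    w <- 2 * sin(pi * a$rho[i] / 6)
    Z[cols, a$parameter[i]] <- w * s + sqrt(1 - w^2) * stats::rnorm(length(cols))
  }
  scales <- .chem_scales()
  vals <- Z
  for (p in params) {
    sc <- scales[[p]]
    if (is.null(sc)) sc <- c(type = 1, loc = 100, spread = 1)
    vals[, p] <- if (sc[["type"]] == 1) sc[["loc"]] * exp(sc[["spread"]] * Z[, p])
                 else sc[["loc"]] + sc[["spread"]] * Z[, p]
  }
  list(chem = chemistry_table(vals), resolved = resolved)
}

#' Generate a synthetic community with recorded ground truth
#'
#' Draws an OTU count table by (1) constructing per-sample expected
#' relative-abundance vectors that honor the planted structure (generalists
#' abundant in every sample of their habitat, specialists abundant in their
#' 1-2 designated samples and exactly absent elsewhere, core background
#' present everywhere below threshold, log-normal background renormalized to
#' the remaining mass), then (2) multinomial sampling at the configured
#' depths (optionally Dirichlet-overdispersed). Chemistry parameters are
#' generated with Spearman-calibrated monotone associations to the planted
#' OTUs' realized abundances. Fully reproducible given the seed.
#'
#' @param config a [community_config].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of class `synthetic_community` with elements `otu`
#'   (an [otu_table] carrying the taxonomy as attribute), `chemistry`,
#'   `taxonomy`, and `truth` — a list with `labels` (data.frame `otu_id`,
#'   `environment`, `label`), `core` (per-environment id sets), planted
#'   `associations` (with resolved `otu_id`), `expected_ra` (the expectation
#'   matrix), `dominant` (per-environment expected core share), `regime`
#'   (`"structured"`), and `seed`.
#' @export
generate_community <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "community_config"))
  with_seed(seed, {
    parts <- .build_expectations(config)
    counts <- .draw_counts(parts$E, config)
    tax <- .make_taxonomy(config, parts$plan, parts$bg_ids)
    ot <- otu_table(counts, parts$sample_env)
    attr(ot, "taxonomy") <- tax
    relab <- to_relative_abundance(counts)
    chem <- .make_chemistry(config, relab, parts$sample_env, parts$plan)

    labels <- do.call(rbind, lapply(config$environments, function(env) {
      pl <- parts$plan[[env]]
      lab <- rep("other", config$n_otus)
      names(lab) <- rownames(counts)
      lab[pl$generalists] <- "generalist"
      lab[pl$specialists] <- "specialist"
      data.frame(otu_id = names(lab), environment = env, label = unname(lab),
                 stringsAsFactors = FALSE)
    }))
    core <- lapply(stats::setNames(config$environments, config$environments),
                   function(env) {
      pl <- parts$plan[[env]]
      sort(c(pl$generalists, pl$core_background))
    })
    assoc <- config$associations
    if (nrow(assoc)) assoc$otu_id <- chem$resolved
    dominant <- NULL
    s <- config$dominant_core_share
    if (!is.null(s)) {
      dominant <- lapply(stats::setNames(names(s), names(s)), function(env) {
        ras <- .gen_ras(config, env)
        others <- (length(ras) - 1) * config$generalist_ra +
          config$n_core_background[[env]] * config$core_background_ra
        list(otu_id = parts$plan[[env]]$generalists[1],
             expected_share_pct = 100 * ras[1] / (ras[1] + others))
      })
    }
    truth <- list(labels = labels, core = core, associations = assoc,
                  expected_ra = parts$E, specialist_sites = parts$spec_sites,
                  dominant = dominant, regime = "structured", seed = seed)
    structure(list(otu = ot, chemistry = chem$chem, taxonomy = tax,
                   truth = truth),
              class = "synthetic_community")
  })
}

#' Generate a community under the pure stochastic-assembly null process
#'
#' All samples are drawn i.i.d. by multinomial sampling from one shared
#' regional relative-abundance vector (log-normal abundances, renormalized):
#' pure sampling noise with no planted sample-level structure. This is the
#' regime the stochasticity test's null model describes, so the test applied
#' to such communities should reject at about its nominal level.
#'
#' @param config a [community_config] (only `environments`, `n_samples`,
#'   `n_otus`, depth settings and `background_sdlog` are used).
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of class `synthetic_community` with `otu` and `truth`
#'   (`regime = "null_process"`, no planted specialists or generalists).
#' @export
generate_null_pair <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "community_config"))
  with_seed(seed, {
    sample_env <- rep(config$environments, config$n_samples[config$environments])
    sample_ids <- .sample_ids(config)
    names(sample_env) <- sample_ids
    regional <- stats::rlnorm(config$n_otus, 0, config$background_sdlog)
    regional <- regional / sum(regional)
    E <- matrix(regional, config$n_otus, length(sample_ids),
                dimnames = list(sprintf("OTU_%04d", seq_len(config$n_otus)),
                                sample_ids))
    counts <- .draw_counts(E, config)
    ot <- otu_table(counts, sample_env)
    labels <- do.call(rbind, lapply(config$environments, function(env) {
      data.frame(otu_id = rownames(counts), environment = env, label = "other",
                 stringsAsFactors = FALSE)
    }))
    truth <- list(labels = labels, core = NULL, associations = NULL,
                  expected_ra = E, regime = "null_process", seed = seed)
    structure(list(otu = ot, chemistry = NULL, taxonomy = NULL, truth = truth),
              class = "synthetic_community")
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("Synthetic community (%s regime)\n", x$truth$regime))
  print(x$otu)
  invisible(x)
}
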