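#' Configuration for the synthetic longitudinal microbiota generator
#'
#' The generator emulates the design of a two-species zoo study: a carnivore
#' ("tiger") and a herbivore ("wildebeest"), several individuals per species,
#' each sampled daily over a short consecutive window, with a handful of
#' individuals contributing a second, independent time series. Structure is
#' planted at three levels -- species core families, individual signature
#' families, and autocorrelated day-to-day fluctuation -- which are exactly
#' the contrasts the clustering pipeline must separate.
#'
#' Latent log-abundances follow a logistic-normal model: for family f on day
#' t of individual i (species s),
#' \deqn{\lambda = \beta_f + \sigma_{species} 1[f \in core(s)] + u_{i,f}
#'   1[f \in signature(i)] + s_{z,f} + \epsilon_{t,f}}
#' with \eqn{\beta_f ~ N(0,1)} drawn once per dataset, individual effects
#' \eqn{u_{i,f} ~ N(0, \sigma_{individual}^2)}, an optional site (zoo) effect
#' \eqn{s_{z,f} ~ N(0, \sigma_{site}^2)}, and \eqn{\epsilon} an AR(1) process
#' with lag-1 correlation `rho_day` and marginal sd `sigma_day`. Sporadic
#' families are masked to zero on days where an independent
#' Bernoulli(`sporadic_presence_prob`) fails; the day profile is the softmax
#' of \eqn{\lambda} over the families present that day; counts are multinomial
#' with depth drawn log-uniformly from `depth_range`; each day of a series is
#' dropped with its species' miss probability (carnivores do not reliably
#' defecate daily).
#'
#' @param n_species Number of species (2 gives the tiger/wildebeest design).
#' @param series_per_species Time series per species.
#' @param n_days Length of the collection window (consecutive days).
#' @param n_families Number of bacterial families.
#' @param families_core_per_species Core families planted per species.
#' @param families_signature_per_individual Signature families drawn per
#'   individual from the shared signature pool.
#' @param sigma_species Log-scale shift added to a species' core families.
#' @param sigma_individual SD of individual signature effects (log scale).
#' @param sigma_day Marginal SD of daily AR(1) noise (log scale).
#' @param rho_day Lag-1 autocorrelation of daily noise, |rho| < 1.
#' @param sporadic_fraction Fraction of families that are only sporadically
#'   present.
#' @param sporadic_presence_prob Per-day presence probability of a sporadic
#'   family.
#' @param miss_prob_per_species Per-species probability that a sampling day
#'   is missed (recycled to `n_species`).
#' @param depth_range Range of per-sample sequencing depth; depths are drawn
#'   log-uniformly between the two values.
#' @param repeat_individuals Per species, how many individuals contribute two
#'   time series (recycled); individuals per species is therefore
#'   `series_per_species - repeat_individuals`.
#' @param n_sites Number of sites (zoos) individuals are spread over.
#' @param sigma_site SD of the site effect; 0 (default) disables it.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_species = 2L,
                             series_per_species = 7L,
                             n_days = 8L,
                             n_families = 30L,
                             families_core_per_species = 4L,
                             families_signature_per_individual = 3L,
                             sigma_species = 2.0,
                             sigma_individual = 1.0,
                             sigma_day = 0.5,
                             rho_day = 0.3,
                             sporadic_fraction = 0.2,
                             sporadic_presence_prob = 0.4,
                             miss_prob_per_species = c(0.15, 0.0),
                             depth_range = c(5836L, 230928L),
                             repeat_individuals = c(1L, 2L),
                             n_sites = 3L,
                             sigma_site = 0.0,
                             seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              series_per_species = as.integer(series_per_species),
              n_days = as.integer(n_days),
              n_families = as.integer(n_families),
              families_core_per_species = as.integer(families_core_per_species),
              families_signature_per_individual =
                as.integer(families_signature_per_individual),
              sigma_species = sigma_species,
              sigma_individual = sigma_individual,
              sigma_day = sigma_day,
              rho_day = rho_day,
              sporadic_fraction = sporadic_fraction,
              sporadic_presence_prob = sporadic_presence_prob,
              miss_prob_per_species =
                rep_len(miss_prob_per_species, n_species),
              depth_range = as.numeric(depth_range),
              repeat_individuals = rep_len(as.integer(repeat_individuals),
                                           n_species),
              n_sites = as.integer(n_sites),
              sigma_site = sigma_site,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_species < 1L || series_per_species < 1L || n_days < 1L ||
        n_families < 1L || n_sites < 1L) {
      stop("counts in generator config must be positive")
    }
    probs <- c(sporadic_fraction, sporadic_presence_prob,
               miss_prob_per_species)
    if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
    if (abs(rho_day) >= 1) stop("|rho_day| must be < 1")
    if (any(depth_range <= 0) || depth_range[1L] > depth_range[2L]) {
      stop("depth_range must be positive and ordered")
    }
    if (any(c(sigma_species, sigma_individual, sigma_day, sigma_site) < 0)) {
      stop("sigma parameters must be nonnegative")
    }
    if (any(repeat_individuals < 0L) ||
        any(repeat_individuals >= series_per_species)) {
      stop("repeat_individuals must be in [0, series_per_species)")
    }
    n_core <- n_species * families_core_per_species
    n_sporadic <- round(sporadic_fraction * n_families)
    if (n_core + n_sporadic >= n_families) {
      stop("not enough families for cores + sporadic set; raise n_families")
    }
  })
  invisible(cfg)
}

# Family role layout: species cores first, then the sporadic set, then the
# signature pool / background split of whatever remains.
family_roles <- function(cfg) {
  fam <- sprintf("fam%02d", seq_len(cfg$n_families))
  role <- rep("background", cfg$n_families)
  detail <- rep(NA_character_, cfg$n_families)
  species <- species_names(cfg$n_species)
  idx <- 1L
  for (s in seq_len(cfg$n_species)) {
    take <- idx:(idx + cfg$families_core_per_species - 1L)
    role[take] <- "species-core"
    detail[take] <- species[s]
    idx <- idx + cfg$families_core_per_species
  }
  n_sporadic <- round(cfg$sporadic_fraction * cfg$n_families)
  if (n_sporadic > 0L) {
    take <- idx:(idx + n_sporadic - 1L)
    role[take] <- "sporadic"
    idx <- idx + n_sporadic
  }
  remaining <- cfg$n_families - idx + 1L
  n_pool <- ceiling(remaining / 2)
  n_pool <- max(n_pool, min(cfg$families_signature_per_individual, remaining))
  if (n_pool > 0L) {
    take <- idx:(idx + n_pool - 1L)
    role[take] <- "individual-signature"
  }
  data.frame(family_id = fam, role = role, detail = detail,
             stringsAsFactors = FALSE)
}

species_names <- function(n) {
  if (n == 2L) c("tiger", "wildebeest") else sprintf("species%d", seq_len(n))
}

#' Generate a synthetic longitudinal microbiota dataset
#'
#' Draws one dataset from the model described in [generator_config()]:
#' a count table (samples x families), sample metadata, and the ground truth
#' (series labels plus planted family roles) against which clustering and
#' feature attribution can be scored.
#'
#' Identical configs (including seed) give identical output.
#'
#' @param config A [generator_config()].
#' @return List with elements `counts` (integer matrix, samples x families),
#'   `metadata` (data frame as in [read_metadata()]) and `truth` (list with
#'   data frames `series` and `families`).
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)
  roles <- family_roles(cfg)
  fam <- roles$family_id
  nf <- cfg$n_families
  species <- species_names(cfg$n_species)
  core_sets <- lapply(species, function(s) {
    fam[roles$role == "species-core" & !is.na(roles$detail) &
          roles$detail == s]
  })
  names(core_sets) <- species
  pool <- fam[roles$role == "individual-signature"]
  sporadic <- fam[roles$role == "sporadic"]

  beta <- stats::rnorm(nf)
  names(beta) <- fam
  sites <- sprintf("zoo%d", seq_len(cfg$n_sites))
  site_eff <- matrix(stats::rnorm(cfg$n_sites * nf), cfg$n_sites, nf,
                     dimnames = list(sites, fam)) * cfg$sigma_site

  counts <- NULL
  meta <- list()
  series_truth <- list()
  sig_assign <- list()

  for (s in seq_len(cfg$n_species)) {
    sp <- species[s]
    n_rep <- cfg$repeat_individuals[s]
    n_ind <- cfg$series_per_species - n_rep
    for (i in seq_len(n_ind)) {
      ind <- sprintf("%s_ind%d", sp, i)
      site <- sites[((i - 1L) %% cfg$n_sites) + 1L]
      n_sig <- min(cfg$families_signature_per_individual, length(pool))
      sig <- if (n_sig > 0L) sample(pool, n_sig) else character()
      u_raw <- stats::rnorm(length(pool))
      u <- stats::setNames(numeric(nf), fam)
      u[pool] <- u_raw * cfg$sigma_individual
      u[setdiff(pool, sig)] <- 0
      sig_assign[[ind]] <- sig
      lam_base <- beta + u + site_eff[site, ]
      lam_base[core_sets[[sp]]] <- lam_base[core_sets[[sp]]] + cfg$sigma_species
      n_series <- if (i <= n_rep) 2L else 1L
      for (ts in seq_len(n_series)) {
        sid <- sprintf("%s_ts%d", ind, ts)
        draw <- simulate_series(cfg, lam_base, sporadic, s)
        if (is.null(draw)) next
        rn <- sprintf("%s_d%02d", sid, draw$days)
        rownames(draw$counts) <- rn
        counts <- rbind(counts, draw$counts)
        meta[[sid]] <- data.frame(
          sample_id = rn, species = sp, individual = ind, site = site,
          series = sid, day = draw$days, stringsAsFactors = FALSE)
        series_truth[[sid]] <- data.frame(
          series_id = sid, individual_id = ind, species_label = sp,
          site_id = site, stringsAsFactors = FALSE)
      }
    }
  }
  colnames(counts) <- fam
  storage.mode(counts) <- "integer"
  metadata <- do.call(rbind, unname(meta))
  rownames(metadata) <- NULL
  roles$detail[roles$role == "individual-signature"] <-
    vapply(roles$family_id[roles$role == "individual-signature"],
           function(f) {
             owners <- names(sig_assign)[vapply(sig_assign, function(x)
               f %in% x, logical(1))]
             if (length(owners)) paste(owners, collapse = ",") else NA_character_
           }, character(1))
  truth <- list(series = do.call(rbind, unname(series_truth)),
                families = roles)
  rownames(truth$series) <- NULL
  list(counts = counts, metadata = metadata, truth = truth)
}

# One series: AR(1) day noise, sporadic masking, softmax, multinomial counts.
simulate_series <- function(cfg, lam_base, sporadic, species_idx) {
  nf <- cfg$n_families
  nd <- cfg$n_days
  fam <- names(lam_base)
  z <- matrix(stats::rnorm(nd * nf), nd, nf)
  eps <- matrix(0, nd, nf)
  eps[1L, ] <- z[1L, ]
  if (nd > 1L) {
    scale_inn <- sqrt(1 - cfg$rho_day^2)
    for (t in 2L:nd) {
      eps[t, ] <- cfg$rho_day * eps[t - 1L, ] + scale_inn * z[t, ]
    }
  }
  eps <- eps * cfg$sigma_day
  present <- matrix(TRUE, nd, nf, dimnames = list(NULL, fam))
  if (length(sporadic)) {
    present[, sporadic] <-
      matrix(stats::runif(nd * length(sporadic)) < cfg$sporadic_presence_prob,
             nd, length(sporadic))
  }
  miss <- stats::runif(nd) < cfg$miss_prob_per_species[species_idx]
  if (all(miss)) miss[1L] <- FALSE   # keep at least one day per series
  depths <- round(exp(stats::runif(nd, log(cfg$depth_range[1L]),
                                   log(cfg$depth_range[2L]))))
  keep <- which(!miss)
  cmat <- matrix(0L, length(keep), nf, dimnames = list(NULL, fam))
  for (j in seq_along(keep)) {
    t <- keep[j]
    lam <- lam_base + eps[t, ]
    p <- numeric(nf)
    idx <- which(present[t, ])
    lam_p <- lam[idx] - max(lam[idx])
    p[idx] <- exp(lam_p) / sum(exp(lam_p))
    cmat[j, ] <- as.integer(stats::rmultinom(1L, depths[t], p))
  }
  list(days = keep, counts = cmat)
}

#' Write / read ground truth
#'
#' Serializes a generator ground truth (series labels plus family roles) to a
#' single TSV with a `section` column, re-readable by [read_truth()].
#'
#' @param truth Ground-truth list as returned by [generate_dataset()].
#' @param path Output TSV path.
#' @return `path` invisibly ([write_truth()]); the truth list ([read_truth()]).
#' @export
write_truth <- function(truth, path) {
  ser <- truth$series
  fams <- truth$families
  df <- rbind(
    data.frame(section = "series", id = ser$series_id,
               species = ser$species_label, individual = ser$individual_id,
               site = ser$site_id, role = NA_character_,
               detail = NA_character_, stringsAsFactors = FALSE),
    data.frame(section = "family", id = fams$family_id,
               species = NA_character_, individual = NA_character_,
               site = NA_character_, role = fams$role,
               detail = fams$detail, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          comment.char = "", quote = "")
  ser <- df[df$section == "series", , drop = FALSE]
  fams <- df[df$section == "family", , drop = FALSE]
  list(
    series = data.frame(series_id = ser$id, individual_id = ser$individual,
                        species_label = ser$species, site_id = ser$site,
                        stringsAsFactors = FALSE),
    families = data.frame(family_id = fams$id, role = fams$role,
                          detail = fams$detail, stringsAsFactors = FALSE))
}
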