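#' Simulate a log2 protein matrix with planted co-expression modules
#'
#' Each module gets a latent per-sample template: standard-normal variation
#' plus, for the treatment-affected modules, an additive shift
#' (`effect_size`, log2 units, sign alternating across affected modules)
#' applied to treated samples — for in vitro designs at the requested
#' exposure timepoints, for biopsy designs to the anthracycline-treated
#' patients. By default only the first two modules are affected (one up-,
#' one down-regulated); unaffected module templates are independent
#' standard-normal draws, so distinct modules stay near-orthogonal and the
#' planted partition is identifiable. A member protein is
#' `kme_target * template + N(0, noise_sd)`, shifted to a per-protein log2
#' baseline drawn from Uniform(8, 14); the implied correlation with the
#' template (the planted kME) is `kme_target / sqrt(kme_target^2 + noise_sd^2)`,
#' about 0.90 at the defaults. Background proteins are baseline plus pure
#' noise of matched variance.
#'
#' @param design A design tibble from [generate_invitro_design()] or
#'   [generate_biopsy_design()].
#' @param module_sizes Integer vector of planted module sizes (may be empty
#'   for a pure-noise matrix).
#' @param n_background Number of unstructured background proteins.
#' @param effect_size Additive treatment shift of the module templates, log2
#'   units.
#' @param effect_timepoints For in vitro designs, the exposure timepoints at
#'   which the shift applies. `NULL` (default) shifts treated samples at
#'   every timepoint; pass e.g. `c(72, 168, 240, 336)` to emulate a delayed
#'   (intermediate/chronic) response.
#' @param effect_modules Indices of modules that receive the treatment shift
#'   (default: the first two; shared shifts across many modules would
#'   correlate their templates).
#' @param kme_target Loading of member proteins on their module template.
#' @param noise_sd Protein-level noise standard deviation, log2 units.
#' @param seed Integer seed; all randomness is locally scoped.
#' @return A list with `matrix` (protein x sample tibble of log2 intensities)
#'   and `truth`, a list holding `planted_partition` (tibble: accession,
#'   module), `planted_kme` (tibble: accession, kme), and `effect_profile`
#'   (tibble: module, effect, applied sign).
#' @export
generate_protein_profiles <- function(design, module_sizes,
                                      n_background = 0,
                                      effect_size = 2,
                                      effect_timepoints = NULL,
                                      effect_modules = NULL,
                                      kme_target = 0.9,
                                      noise_sd = 0.436,
                                      seed = 1) {
  if (nrow(design) == 0) abort("empty design")
  if (length(module_sizes) && any(module_sizes < 1)) {
    abort("module_sizes must be positive")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  n_mod <- length(module_sizes)
  if (is.null(effect_modules)) effect_modules <- seq_len(min(2, n_mod))
  samples <- design$sample_id
  ns <- length(samples)

  treated <- rep(FALSE, ns)
  if (all(design$dataset_kind == "biopsy")) {
    treated <- design$patient_group %in% "ant_treated"
  } else {
    treated <- design$compound != "none"
    if (!is.null(effect_timepoints)) {
      treated <- treated & design$timepoint_h %in% effect_timepoints
    }
  }

  with_local_seed(seed, {
    templates <- matrix(0, nrow = max(n_mod, 0), ncol = ns)
    signs <- integer(0)
    if (n_mod > 0) {
      signs <- rep_len(c(1, -1), n_mod)
      for (m in seq_len(n_mod)) {
        tm <- rnorm(ns)
        if (m %in% effect_modules) {
          tm[treated] <- tm[treated] + signs[m] * effect_size
        }
        # standardize so the member-loading arithmetic holds exactly
        templates[m, ] <- as.numeric(scale(tm))
      }
    }
    n_prot <- sum(module_sizes) + n_background
    acc <- sprintf("SYN%04d", seq_len(n_prot))
    module <- c(if (n_mod) rep(paste0("M", seq_len(n_mod)), times = module_sizes)
                else character(0),
                rep("background", n_background))
    x <- matrix(NA_real_, nrow = n_prot, ncol = ns,
                dimnames = list(acc, samples))
    baseline <- runif(n_prot, 8, 14)
    total_sd <- sqrt(kme_target^2 + noise_sd^2)
    for (p in seq_len(n_prot)) {
      if (module[p] == "background") {
        x[p, ] <- baseline[p] + rnorm(ns, sd = max(total_sd, 1e-12))
      } else {
        m <- match(module[p], paste0("M", seq_len(n_mod)))
        x[p, ] <- baseline[p] + kme_target * templates[m, ] +
          rnorm(ns, sd = noise_sd)
      }
    }
    planted_kme <- ifelse(module == "background", 0,
                          kme_target / max(total_sd, 1e-12))
    list(
      matrix = matrix_to_pm(x),
      truth = list(
        planted_partition = tibble::tibble(accession = acc, module = module),
        planted_kme = tibble::tibble(accession = acc, kme = planted_kme),
        effect_profile = tibble::tibble(
          module = if (n_mod) paste0("M", seq_len(n_mod)) else character(),
          effect = ifelse(seq_len(n_mod) %in% effect_modules,
                          signs * effect_size, 0)
        ),
        templates = if (n_mod) {
          matrix(templates, nrow = n_mod,
                 dimnames = list(paste0("M", seq_len(n_mod)), samples))
        } else NULL
      )
    )
  })
}

#' Expand a protein matrix into a synthetic peptide-level table
#'
#' Each protein is expanded into several peptides with multiplicative,
#' log-normal response factors on the linear intensity scale (LC-MS peptides
#' ionize with very different efficiencies). A configurable fraction of
#' peptides is additionally split across charge states (2+/3+/4+) and
#' modification variants whose intensities sum back to the peptide total, so
#' charge/modification consolidation is exercised losslessly.
#'
#' @param proteins Protein x sample tibble of log2 intensities.
#' @param peptides_per_protein Length-2 integer range (min, max) of peptides
#'   per protein.
#' @param variant_fraction Fraction of peptides emitted as multiple
#'   charge/modification rows.
#' @param response_sdlog sdlog of the log-normal peptide response factors.
#' @param seed Integer seed.
#' @return A peptide tibble with columns `peptide`, `protein`, `charge`,
#'   `modification`, then one linear-intensity column per sample.
#' @export
generate_peptides <- function(proteins, peptides_per_protein = c(3, 6),
                              variant_fraction = 0.2, response_sdlog = 1,
                              seed = 1) {
  stopifnot(length(peptides_per_protein) == 2)
  if (peptides_per_protein[1] < 1) abort("need at least 1 peptide per protein")
  check_fraction(variant_fraction, "variant_fraction")
  m <- pm_to_matrix(proteins)
  linear <- 2^m
  mods <- c("carbamidomethyl", "oxidation", "deamidated")
  with_local_seed(seed, {
    rows <- vector("list", nrow(linear) * 2L)
    k <- 0L
    for (p in seq_len(nrow(linear))) {
      acc <- rownames(linear)[p]
      n_pep <- if (peptides_per_protein[1] == peptides_per_protein[2]) {
        peptides_per_protein[1]
      } else {
        sample(seq(peptides_per_protein[1], peptides_per_protein[2]), 1)
      }
      f <- exp(rnorm(n_pep, sd = response_sdlog))
      for (j in seq_len(n_pep)) {
        pep_key <- sprintf("%s_pep%02d", acc, j)
        base <- f[j] * linear[p, ]
        if (runif(1) < variant_fraction) {
          n_var <- sample(2:3, 1)
          w <- runif(n_var)
          w <- w / sum(w)
          charges <- sample(2:4, n_var)
          modv <- c("none", sample(mods, n_var - 1))
          for (v in seq_len(n_var)) {
            k <- k + 1L
            rows[[k]] <- tibble::tibble(
              peptide = pep_key, protein = acc,
              charge = as.integer(charges[v]), modification = modv[v],
              !!!as.list(w[v] * base)
            )
          }
        } else {
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            peptide = pep_key, protein = acc,
            charge = 2L, modification = "none",
            !!!as.list(base)
          )
        }
      }
    }
    dplyr::bind_rows(rows[seq_len(k)])
  })
}

#' Inject missing values into an intensity table
#'
#' Censors cells either completely at random (MCAR) or preferentially at low
#' intensity (the mechanism typical of label-free LC-MS, where low-abundance
#' ions drop below the detection limit). The number of missing cells is set
#' so the realized overall missing fraction matches `target_rate` exactly up
#' to rounding.
#'
#' @param x A protein or peptide tibble (feature columns plus numeric sample
#'   columns).
#' @param mechanism `"intensity_dependent"` (default) or `"MCAR"`.
#' @param target_rate Overall fraction of cells missing after injection, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return The same tibble with `NA` in censored cells.
#' @export
inject_missingness <- function(x, mechanism = c("intensity_dependent", "MCAR"),
                               target_rate = 0.2, seed = 1) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(target_rate) || target_rate < 0 || target_rate >= 1) {
    abort("`target_rate` must be in [0, 1)")
  }
  if (target_rate == 0) return(x)
  id_cols <- intersect(names(x),
                       c("accession", "peptide", "protein", "charge",
                         "modification"))
  val_cols <- setdiff(names(x), id_cols)
  v <- as.matrix(x[val_cols])
  n_cells <- length(v)
  n_target <- round(target_rate * n_cells)
  already <- sum(is.na(v))
  n_new <- max(n_target - already, 0)
  if (n_new == 0) return(x)
  present <- which(!is.na(v))
  with_local_seed(seed, {
    if (mechanism == "MCAR") {
      drop_idx <- sample(present, n_new)
    } else {
      vals <- v[present]
      r <- rank(vals, ties.method = "average") / length(vals)
      w <- (1 - r + 1 / length(vals))^4
      drop_idx <- present[sample.int(length(present), n_new, prob = w)]
    }
    v[drop_idx] <- NA_real_
  })
  x[val_cols] <- tibble::as_tibble(v, .name_repair = "minimal")
  x
}

#' Simulate a protein-protein interaction graph with planted hubs
#'
#' Draws a sparse background graph whose degrees are approximately
#' Poisson(`background_degree_mean`), then wires each designated hub to
#' random partners until it reaches `hub_degree` connections. The result is a
#' simple undirected edge list; nodes may be isolated.
#'
#' @param proteins Character vector of node accessions.
#' @param hub_count Number of planted hubs (taken from the head of
#'   `proteins`).
#' @param hub_degree Minimum degree of each planted hub.
#' @param background_degree_mean Mean background degree.
#' @param seed Integer seed.
#' @return A list with `edges` (tibble: from, to) and `hubs` (character
#'   vector of planted hub accessions).
#' @export
generate_ppi <- function(proteins, hub_count = 4, hub_degree = 30,
                         background_degree_mean = 3, seed = 1) {
  n <- length(proteins)
  if (hub_count > 0 && hub_degree >= n) {
    abort("`hub_degree` must be smaller than the number of proteins")
  }
  stopifnot(hub_count >= 0, background_degree_mean >= 0)
  hubs <- proteins[seq_len(hub_count)]
  with_local_seed(seed, {
    edges <- matrix(integer(0), ncol = 2)
    if (background_degree_mean > 0 && n > 1) {
      p_edge <- min(background_degree_mean / (n - 1), 1)
      pairs <- utils::combn(n, 2)
      keep <- stats::runif(ncol(pairs)) < p_edge
      edges <- t(pairs[, keep, drop = FALSE])
    }
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    have <- key(edges)
    deg <- tabulate(c(edges), nbins = n)
    for (h in seq_len(hub_count)) {
      while (deg[h] < hub_degree) {
        cand <- sample(setdiff(seq_len(n), h), hub_degree - deg[h])
        new <- cbind(pmin(h, cand), pmax(h, cand))
        fresh <- !key(new) %in% have
        if (any(fresh)) {
          new <- new[fresh, , drop = FALSE]
          edges <- rbind(edges, new)
          have <- c(have, key(new))
          deg <- tabulate(c(edges), nbins = n)
        }
      }
    }
    list(
      edges = tibble::tibble(from = proteins[edges[, 1]],
                             to = proteins[edges[, 2]]),
      hubs = hubs
    )
  })
}

#' Simulate a disease gene set overlapping planted modules
#'
#' Samples a fraction of each requested planted module plus a sprinkle of
#' background proteins, emulating a disease association catalogue that is
#' enriched in some co-expression modules.
#'
#' @param partition Tibble (accession, module) — typically the
#'   `planted_partition` from [generate_protein_profiles()].
#' @param module_fraction Fraction sampled from each targeted module.
#' @param modules Modules to enrich (default: all non-background).
#' @param background_fraction Fraction sampled from the remaining proteins.
#' @param seed Integer seed.
#' @return Character vector of accessions.
#' @export
generate_disease_set <- function(partition, module_fraction = 0.3,
                                 modules = NULL, background_fraction = 0.02,
                                 seed = 1) {
  check_fraction(module_fraction, "module_fraction")
  check_fraction(background_fraction, "background_fraction")
  if (is.null(modules)) {
    modules <- setdiff(unique(partition$module), "background")
  }
  with_local_seed(seed, {
    inside <- partition$accession[partition$module %in% modules]
    outside <- setdiff(partition$accession, inside)
    c(
      sample(inside, round(module_fraction * length(inside))),
      sample(outside, round(background_fraction * length(outside)))
    )
  })
}
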