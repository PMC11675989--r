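#' Configuration for the synthetic multi-breed cohort generator
#'
#' Bundles and validates every knob of the simulator. Defaults describe a
#' desk-scale cohort with the structure of a multi-breed commercial-breeding
#' population: several moderately differentiated breeds, mild within-breed
#' inbreeding, block-wise linkage disequilibrium, sporadic missingness, and
#' fear phenotypes driven by kennel/sex/size/age fixed effects plus a
#' polygenic component at a target heritability.
#'
#' @param n_breeds Number of breeds.
#' @param n_per_breed Dogs per breed.
#' @param n_snps Number of autosomal SNPs.
#' @param n_chromosomes Number of autosomes (dog karyotype: 38).
#' @param fst_per_breed Breed differentiation (Balding-Nichols Fst), scalar or
#'   one value per breed, each in \[0, 1).
#' @param inbreeding_per_breed Within-breed inbreeding coefficient, scalar or
#'   per breed, each in \[-0.3, 0.5\].
#' @param missing_rate Fraction of genotype calls set missing, in \[0, 1).
#' @param n_causal Causal SNPs per behavioral component.
#' @param h2_target Target narrow-sense heritability of each latent component,
#'   in \[0, 1\].
#' @param causal_var_frac Fraction of the genetic variance carried by the
#'   causal SNPs (the remainder is spread polygenically).
#' @param ld_block_len SNPs per LD block; adjacent SNPs within a block share
#'   haplotype state with probability \code{ld_rho}.
#' @param ld_rho Within-block haplotype copying probability, in \[0, 1).
#' @param n_facilities Number of kennels dogs are housed in.
#' @param fixed_effects List of fixed-effect magnitudes on the latent scale
#'   (unit total genetic-plus-residual variance): \code{facility_sd},
#'   \code{sex_male}, \code{size_sd}, \code{age_slope}.
#' @param female_frac Fraction of females in the cohort.
#' @param item_noise_sd Item-level noise added to the latent component before
#'   discretization to the 0/1/2 assessment scale.
#' @param seed Integer seed; every generator call is deterministic given it.
#'
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_breeds = 6,
                       n_per_breed = 100,
                       n_snps = 5000,
                       n_chromosomes = 38,
                       fst_per_breed = 0.15,
                       inbreeding_per_breed = 0.05,
                       missing_rate = 0.01,
                       n_causal = 20,
                       h2_target = 0.3,
                       causal_var_frac = 0.5,
                       ld_block_len = 10,
                       ld_rho = 0.7,
                       n_facilities = 40,
                       fixed_effects = list(facility_sd = 0.3,
                                            sex_male = 0.2,
                                            size_sd = 0.2,
                                            age_slope = 0.05),
                       female_frac = 0.83,
                       item_noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              n_per_breed = as.integer(n_per_breed),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              fst_per_breed = rep_len(fst_per_breed, n_breeds),
              inbreeding_per_breed = rep_len(inbreeding_per_breed, n_breeds),
              missing_rate = missing_rate,
              n_causal = as.integer(n_causal),
              h2_target = h2_target,
              causal_var_frac = causal_var_frac,
              ld_block_len = as.integer(ld_block_len),
              ld_rho = ld_rho,
              n_facilities = as.integer(n_facilities),
              fixed_effects = fixed_effects,
              female_frac = female_frac,
              item_noise_sd = item_noise_sd,
              seed = as.integer(seed))
  .check_config_field(cfg$n_breeds >= 1, "n_breeds")
  .check_config_field(cfg$n_per_breed >= 1, "n_per_breed")
  .check_config_field(cfg$n_snps >= 1, "n_snps")
  .check_config_field(cfg$n_chromosomes >= 1, "n_chromosomes")
  .check_config_field(all(cfg$fst_per_breed >= 0 & cfg$fst_per_breed < 1),
                      "fst_per_breed")
  .check_config_field(all(cfg$inbreeding_per_breed >= -0.3 &
                            cfg$inbreeding_per_breed <= 0.5),
                      "inbreeding_per_breed")
  .check_config_field(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
                      "missing_rate")
  .check_config_field(cfg$n_causal >= 0 && cfg$n_causal <= cfg$n_snps,
                      "n_causal")
  .check_config_field(cfg$h2_target >= 0 && cfg$h2_target <= 1, "h2_target")
  .check_config_field(cfg$causal_var_frac >= 0 && cfg$causal_var_frac <= 1,
                      "causal_var_frac")
  .check_config_field(cfg$ld_block_len >= 1, "ld_block_len")
  .check_config_field(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho")
  .check_config_field(cfg$female_frac >= 0 && cfg$female_frac <= 1,
                      "female_frac")
  class(cfg) <- "sim_config"
  cfg
}

.check_config_field <- function(ok, field) {
  if (!isTRUE(ok)) {
    stop("invalid simulation configuration: field '", field,
         "' is out of range", call. = FALSE)
  }
}

#' Simulate multi-breed SNP genotypes with known structure
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.5); per-breed
#' frequencies follow the Balding-Nichols model
#' Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst). Within a breed, each dog carries two
#' haplotypes; linkage disequilibrium is induced block-wise by copying the
#' previous marker's allele with probability \code{ld_rho} inside blocks of
#' \code{ld_block_len} markers, and within-breed inbreeding F is induced by
#' making the second haplotype identical by descent to the first at each
#' marker with probability F, which yields the excess-homozygosity genotype
#' frequencies P(hom) = p^2 + Fp(1-p) etc. Missing calls are placed uniformly
#' at random. Dosages are oriented to the cohort minor allele.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{geno} (samples x variants minor-allele dosage
#'   matrix, \code{NA} = missing), \code{variants} (data frame: id, chrom,
#'   pos, allele_minor, allele_major, maf, call_rate, polymorphic, indel),
#'   \code{samples} (data frame: id, breed, facility, sex, age, size_class),
#'   and \code{truth} (per-individual true F, per-breed Fst, breed allele
#'   frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  n <- config$n_breeds * config$n_per_breed

  p_anc <- stats::runif(m, 0.05, 0.5)
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(idx) {
    cumsum(sample(1e3:5e4, length(idx), replace = TRUE))
  }), use.names = FALSE)
  block <- (seq_len(m) - 1L) %/% config$ld_block_len
  new_block <- c(TRUE, diff(block) != 0 | diff(chrom) != 0)

  geno <- matrix(NA_integer_, n, m)
  breed_freq <- matrix(NA_real_, m, config$n_breeds)
  for (b in seq_len(config$n_breeds)) {
    fst <- config$fst_per_breed[b]
    fb <- config$inbreeding_per_breed[b]
    p_b <- if (fst > 0) {
      stats::rbeta(m, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    } else {
      p_anc
    }
    p_b <- pmin(pmax(p_b, 1e-4), 1 - 1e-4)
    breed_freq[, b] <- p_b
    nb <- config$n_per_breed
    h1 <- matrix(0L, nb, m)
    h2raw <- matrix(0L, nb, m)  # chain state, untouched by the IBD overlay
    h2out <- matrix(0L, nb, m)
    for (j in seq_len(m)) {
      draw1 <- stats::rbinom(nb, 1L, p_b[j])
      draw2 <- stats::rbinom(nb, 1L, p_b[j])
      if (new_block[j]) {
        h1[, j] <- draw1
        h2raw[, j] <- draw2
      } else {
        keep1 <- stats::runif(nb) < config$ld_rho
        keep2 <- stats::runif(nb) < config$ld_rho
        h1[, j] <- ifelse(keep1, h1[, j - 1L], draw1)
        h2raw[, j] <- ifelse(keep2, h2raw[, j - 1L], draw2)
      }
      h2out[, j] <- h2raw[, j]
      if (fb > 0) {
        ibd <- stats::runif(nb) < fb
        h2out[ibd, j] <- h1[ibd, j]
      } else if (fb < 0) {
        # negative F: force heterozygosity above HW by flipping matching pairs
        flip <- stats::runif(nb) < -fb
        same <- h1[, j] == h2raw[, j]
        h2out[flip & same, j] <- 1L - h2raw[flip & same, j]
      }
    }
    rows <- (b - 1L) * nb + seq_len(nb)
    geno[rows, ] <- h1 + h2out
  }

  sample_ids <- sprintf("dog%04d", seq_len(n))
  variant_ids <- sprintf("snp%05d", seq_len(m))
  rownames(geno) <- sample_ids
  colnames(geno) <- variant_ids

  # orient to cohort minor allele
  freq <- colMeans(geno) / 2
  flip <- freq > 0.5
  geno[, flip] <- 2L - geno[, flip]
  allele_minor <- ifelse(flip, "A", "B")
  allele_major <- ifelse(flip, "B", "A")

  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    geno[matrix(miss, n, m)] <- NA_integer_
  }

  variants <- data.frame(id = variant_ids,
                         chrom = as.character(chrom),
                         pos = pos,
                         allele_minor = allele_minor,
                         allele_major = allele_major,
                         maf = pmin(colMeans(geno, na.rm = TRUE) / 2,
                                    1 - colMeans(geno, na.rm = TRUE) / 2),
                         call_rate = colMeans(!is.na(geno)),
                         polymorphic = apply(geno, 2, function(x) {
                           length(unique(x[!is.na(x)])) > 1L
                         }),
                         indel = FALSE,
                         stringsAsFactors = FALSE)

  breeds <- rep(sprintf("breed%02d", seq_len(config$n_breeds)),
                each = config$n_per_breed)
  size_levels <- c("XS", "S", "M", "L", "XL")
  breed_size <- sample(size_levels, config$n_breeds, replace = TRUE)
  samples <- data.frame(id = sample_ids,
                        breed = breeds,
                        facility = sprintf("fac%02d",
                                           sample.int(config$n_facilities, n,
                                                      replace = TRUE)),
                        sex = ifelse(stats::runif(n) < config$female_frac,
                                     "F", "M"),
                        age = stats::runif(n, 1, 10),
                        size_class = breed_size[rep(seq_len(config$n_breeds),
                                                    each = config$n_per_breed)],
                        stringsAsFactors = FALSE)

  truth <- list(true_F_per_individual = rep(config$inbreeding_per_breed,
                                            each = config$n_per_breed),
                fst_per_breed = config$fst_per_breed,
                breed_freq = breed_freq)

  list(geno = geno, variants = variants, samples = samples, truth = truth)
}

# item -> latent-component map used by the generator (and as the default
# grouping the PCA labeller expects)
.item_groups <- function() {
  list(SF = c("approach", "open", "reach", "touch"),
       FM = c("treat", "ball", "squeaky", "problem"),
       NSF = c("mat", "leash", "cone", "statue"),
       SR = c("umbrella", "umbrella_recovery"))
}

#' Simulate behavioral assessment item scores with known genetic architecture
#'
#' For each of four latent behavioral components (social fear SF, food
#' motivation FM, non-social fear NSF, startle response SR) a continuous
#' latent score is built as fixed effects (facility, sex, size class, age)
#' plus a genetic term (a handful of causal SNPs plus a polygenic tail over
#' all remaining markers) plus residual noise; genetic and residual parts are
#' scaled so the genetic fraction of their summed variance equals
#' \code{h2_target}. Assessment items are the latent component plus item
#' noise, discretized to the 0/1/2 scale at tertiles (binary items at the
#' median). Higher scores mean a more confident, less fearful response.
#'
#' @param geno Dosage matrix from \code{\link{simulate_genotypes}} (missing
#'   entries are mean-filled internally for phenotype construction).
#' @param samples Sample table from \code{\link{simulate_genotypes}}.
#' @param config The same \code{\link{sim_config}}.
#' @return A list with \code{behavior} (data frame of item scores, one row
#'   per dog) and \code{truth} (causal ids/effects per component, realized
#'   heritability per component, latent component scores, fixed-effect
#'   values).
#' @export
simulate_phenotypes <- function(geno, samples, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(geno) != nrow(samples)) {
    stop("genotype and sample tables disagree on the number of dogs")
  }
  if (config$h2_target > 0 && config$n_snps == 0) {
    stop("invalid simulation configuration: h2_target > 0 requires at least ",
         "one SNP to carry genetic variance")
  }
  set.seed(config$seed + 1L)
  n <- nrow(geno)
  m <- ncol(geno)

  X <- geno
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)

  fe <- config$fixed_effects
  fac_lev <- sort(unique(samples$facility))
  size_lev <- sort(unique(samples$size_class))
  fac_eff <- stats::rnorm(length(fac_lev), 0, fe$facility_sd)
  size_eff <- stats::rnorm(length(size_lev), 0, fe$size_sd)
  names(fac_eff) <- fac_lev
  names(size_eff) <- size_lev
  fixed <- fac_eff[samples$facility] +
    ifelse(samples$sex == "M", fe$sex_male, 0) +
    size_eff[samples$size_class] +
    fe$age_slope * (samples$age - mean(samples$age))

  comps <- c("SF", "FM", "NSF", "SR")
  latent <- matrix(0, n, length(comps), dimnames = list(samples$id, comps))
  causal_ids <- list()
  causal_effects <- list()
  realized_h2 <- numeric(length(comps))
  names(realized_h2) <- comps

  for (k in seq_along(comps)) {
    g <- numeric(n)
    ids <- character(0)
    eff <- numeric(0)
    if (config$h2_target > 0) {
      cvf <- if (config$n_causal > 0) config$causal_var_frac else 0
      g_causal <- numeric(n)
      if (config$n_causal > 0) {
        c_idx <- sample.int(m, config$n_causal)
        beta <- stats::rnorm(config$n_causal)
        g_causal <- drop(Xc[, c_idx, drop = FALSE] %*% beta)
        if (stats::var(g_causal) > 0 && cvf > 0) {
          sc <- sqrt(cvf * config$h2_target / stats::var(g_causal))
          g_causal <- g_causal * sc
          beta <- beta * sc
        }
        ids <- colnames(geno)[c_idx]
        eff <- beta
      }
      g_poly <- numeric(n)
      if (cvf < 1) {
        a <- stats::rnorm(m, 0, 1 / sqrt(m))
        g_poly <- drop(Xc %*% a)
        if (stats::var(g_poly) > 0) {
          g_poly <- g_poly * sqrt((1 - cvf) * config$h2_target /
                                    stats::var(g_poly))
        }
      }
      g <- g_causal + g_poly
      # causal and polygenic parts share markers, so rescale their sum (and
      # the recorded effects with it) to pin var(g) at h2_target exactly
      if (stats::var(g) > 0) {
        sc2 <- sqrt(config$h2_target / stats::var(g))
        g <- g * sc2
        eff <- eff * sc2
      }
    }
    e <- stats::rnorm(n)
    if (config$h2_target < 1) {
      e <- e * sqrt((1 - config$h2_target) / stats::var(e))
    } else {
      e <- e * 0
    }
    latent[, k] <- fixed + g + e
    vg <- stats::var(g)
    realized_h2[k] <- if (vg + stats::var(e) > 0) vg / (vg + stats::var(e)) else 0
    causal_ids[[comps[k]]] <- ids
    causal_effects[[comps[k]]] <- eff
  }

  groups <- .item_groups()
  binary_items <- c("touch", "treat")
  behavior <- data.frame(id = samples$id, stringsAsFactors = FALSE)
  for (comp in names(groups)) {
    for (item in groups[[comp]]) {
      raw <- latent[, comp] + stats::rnorm(n, 0, config$item_noise_sd)
      if (item %in% binary_items) {
        behavior[[item]] <- as.integer(raw > stats::median(raw))
      } else {
        cuts <- stats::quantile(raw, c(1 / 3, 2 / 3))
        behavior[[item]] <- as.integer(cut(raw, c(-Inf, cuts, Inf))) - 1L
      }
    }
  }
  # aggression flag (0 = aggressive episode observed, 1 = none), rare by design
  behavior$no_aggression <- as.integer(latent[, "SF"] >
                                         stats::quantile(latent[, "SF"], 0.03))

  truth <- list(causal_ids = causal_ids,
                causal_effects = causal_effects,
                realized_h2 = realized_h2,
                latent = latent,
                fixed_effect_values = fixed,
                facility_effects = fac_eff,
                size_effects = size_eff)
  list(behavior = behavior, truth = truth)
}

#' Build a variant manifest with fixed category counts
#'
#' Produces a pre-QC variant manifest containing exactly
#' \code{n_nonautosomal} markers on non-autosomal or unmapped contigs
#' (X/Y/MT/un) and, among the autosomal remainder, exactly
#' \code{n_mono_or_indel} monomorphic-or-indel entries, randomly interleaved
#' with the autosomal polymorphic SNPs.
#'
#' @param n_total Total variants.
#' @param n_nonautosomal Variants on X/Y/MT or unmapped contigs.
#' @param n_mono_or_indel Autosomal variants that are monomorphic or indels.
#' @param seed Integer seed for the interleaving and category placement.
#' @param n_chromosomes Number of autosomes for label assignment.
#' @return A variant table (id, chrom, pos, polymorphic, indel).
#' @export
make_variant_manifest <- function(n_total, n_nonautosomal, n_mono_or_indel,
                                  seed = 1L, n_chromosomes = 38) {
  if (n_total < 0 || n_nonautosomal < 0 || n_mono_or_indel < 0) {
    stop("variant category counts must be non-negative")
  }
  if (n_nonautosomal + n_mono_or_indel > n_total) {
    stop("category counts exceed the total number of variants")
  }
  set.seed(as.integer(seed))
  category <- sample(rep(c("nonauto", "mono_indel", "auto_poly"),
                         c(n_nonautosomal, n_mono_or_indel,
                           n_total - n_nonautosomal - n_mono_or_indel)))
  chrom <- character(n_total)
  is_nonauto <- category == "nonauto"
  chrom[is_nonauto] <- sample(c("X", "Y", "MT", "un"), sum(is_nonauto),
                              replace = TRUE)
  chrom[!is_nonauto] <- as.character(sample.int(n_chromosomes,
                                                sum(!is_nonauto),
                                                replace = TRUE))
  is_mono_indel <- category == "mono_indel"
  indel <- logical(n_total)
  # split the monomorphic-or-indel pool roughly in half between the two flags
  indel[is_mono_indel] <- stats::runif(sum(is_mono_indel)) < 0.5
  polymorphic <- !(is_mono_indel & !indel)

  data.frame(id = sprintf("var%07d", seq_len(n_total)),
             chrom = chrom,
             pos = sample.int(1e8, n_total, replace = TRUE),
             polymorphic = polymorphic,
             indel = indel,
             stringsAsFactors = FALSE)
}
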