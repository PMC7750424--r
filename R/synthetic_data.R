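#' Table-style signal-peptide fixture
#'
#' The 14 consensus/representative signal peptides of the six kappa
#' light-chain families (Vk1-Vk6), the seven heavy-chain families
#' (VH1-VH7), and the myeloma-derived IgE leader, shipped with the package
#' as a plain FASTA file. VH1 and VH7 share an identical amino-acid
#' sequence and are kept as separate records.
#'
#' @return Data frame as from [parse_sp_fasta()], 14 rows.
#' @export
#' @examples
#' sp <- sp_fixture()
#' subset(sp, family == "IgE")$sequence
sp_fixture <- function() {
  path <- system.file("extdata", "sp_families.fasta", package = "aacap",
                      mustWork = TRUE)
  parse_sp_fasta(path)
}

#' DMEM supply and full-length antibody demand fixture
#'
#' The per-amino-acid molecule supply of a standard DMEM formulation
#' (molecule counts in units of 1e20; five non-essential amino acids --
#' A, D, E, N, P -- are absent) and the representative average amino-acid
#' demand of a full-length antibody, both shipped as CSV fixtures.
#'
#' @return List with `supply` (named molecule counts) and `demand` (named
#'   residues per antibody copy), each over the 20-letter alphabet.
#' @export
#' @examples
#' med <- media_fixture()
#' med$demand["W"]
media_fixture <- function() {
  supply <- read_media_csv(system.file("extdata", "dmem_media.csv",
                                       package = "aacap", mustWork = TRUE))
  demand <- read_demand_csv(system.file("extdata", "antibody_demand.csv",
                                        package = "aacap", mustWork = TRUE))
  list(supply = supply, demand = demand)
}

#' Configuration for the synthetic variant-production generator
#'
#' Defaults emulate the statistical shape of a transient co-transfection
#' variant panel: 168 variants, class shares 0.40 / 0.40 / 0.20 with "high"
#' producers the deliberate minority, count features perturbed around the
#' full-length antibody composition, and a planted linear effect of
#' standardised counts on the production rate. The planted coefficients
#' echo the qualitative trends of the analysis (more W, K, I associated
#' with better production; more L, S with poorer).
#'
#' @param n_variants Number of variants (>= 3).
#' @param proportions Target class shares (low, medium, high); must sum
#'   to 1.
#' @param coefficients Named numeric vector over (a subset of) the 20
#'   amino acids: planted effects per SD of the count feature.
#' @param noise_sd Gaussian noise SD added to the rate, in percentage
#'   points.
#' @param perturb_mag Poisson magnitude of the symmetric integer count
#'   perturbation around the base composition.
#' @param base_composition Named base count vector; defaults to the
#'   full-length antibody demand fixture.
#' @param rate_max Ceiling of the rate map in percent (rates may exceed
#'   100, as observed experimentally).
#' @param low_cut,high_cut Labelling thresholds in percent.
#' @param seed Integer seed governing all randomness.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_variants = 168,
                             proportions = c(low = 0.40, medium = 0.40,
                                             high = 0.20),
                             coefficients = c(W = 1.0, K = 0.7, I = 0.5,
                                              L = -0.8, S = -0.6),
                             noise_sd = 3, perturb_mag = 3,
                             base_composition = NULL, rate_max = 250,
                             low_cut = 20, high_cut = 70, seed = 1L) {
  stopifnot(n_variants >= 3, length(proportions) == 3,
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0),
            noise_sd >= 0, perturb_mag >= 0, rate_max > high_cut)
  if (any(proportions > 0 & proportions * n_variants < 1)) {
    stop("a class with positive target share needs n_variants large enough ",
         "for at least one member")
  }
  if (is.null(base_composition)) base_composition <- media_fixture()$demand
  beta <- stats::setNames(numeric(20), aa_alphabet())
  if (!all(names(coefficients) %in% aa_alphabet())) {
    stop("coefficient names must be one-letter amino-acid codes")
  }
  beta[names(coefficients)] <- coefficients
  structure(
    list(n_variants = n_variants, proportions = proportions,
         coefficients = beta, noise_sd = noise_sd,
         perturb_mag = perturb_mag,
         base_composition = base_composition[aa_alphabet()],
         rate_max = rate_max, low_cut = low_cut, high_cut = high_cut,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic variant-production dataset
#'
#' Per variant, amino-acid counts are the base composition plus symmetric
#' integer Poisson perturbations (clipped at zero). A latent score is the
#' planted affine function of the z-scored counts; the production rate is a
#' monotone affine-logistic squashing of that score onto (0, `rate_max`)%,
#' calibrated by quantile matching so the realised class shares land on the
#' configured proportions, plus Gaussian noise. Labels follow
#' [categorize()]. The whole dataset is reproducible from the config seed.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_dataset` with `records` (data frame:
#'   `id`, the 20 count columns, `production_rate`, `label`) and `truth`
#'   (planted coefficients, rate-map parameters, latent scores, seed).
#' @export
#' @examples
#' ds <- generate_variants(generator_config(n_variants = 50, seed = 7))
#' table(ds$records$label)
generate_variants <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_variants
  set.seed(config$seed)

  base <- config$base_composition
  counts <- sapply(aa_alphabet(), function(a) {
    pmax(0L, base[[a]] + stats::rpois(n, config$perturb_mag) -
               stats::rpois(n, config$perturb_mag))
  })
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(NULL, aa_alphabet()))

  std <- standardizer(counts)
  Z <- apply_standardizer(counts, std)
  latent <- drop(Z %*% config$coefficients)

  # Quantile calibration: place the class cut points of the latent score at
  # the target cumulative shares, then choose the logistic map so those
  # points land exactly on the rate thresholds.
  p <- config$proportions
  q <- stats::quantile(latent, probs = c(p[1], p[1] + p[2]), names = FALSE,
                       type = 7)
  target <- stats::qlogis(c(config$low_cut, config$high_cut) / config$rate_max)
  if (q[2] - q[1] < 1e-12) {
    a <- 1; m <- q[1]  # degenerate latent spread (e.g. all-zero coefficients)
  } else {
    a <- (target[2] - target[1]) / (q[2] - q[1])
    m <- q[1] - target[1] / a
  }
  rate <- config$rate_max * stats::plogis(a * (latent - m))
  rate <- pmax(0, rate + stats::rnorm(n, 0, config$noise_sd))
  label <- categorize(rate, config$low_cut, config$high_cut)

  records <- data.frame(id = sprintf("variant_%03d", seq_len(n)),
                        counts, production_rate = rate, label = label,
                        stringsAsFactors = FALSE)
  structure(
    list(records = records,
         truth = list(coefficients = config$coefficients,
                      rate_map = list(slope = a, midpoint = m,
                                      rate_max = config$rate_max),
                      latent = latent, config = config)),
    class = "synthetic_dataset"
  )
}

#' Write a variant dataset CSV
#'
#' Columns: `id`, the 20 amino-acid counts in alphabetical order,
#' `production_rate`. Labels are derivable and never stored.
#'
#' @param dataset A `synthetic_dataset` or a records data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_csv <- function(dataset, path) {
  records <- if (inherits(dataset, "synthetic_dataset")) dataset$records else dataset
  out <- records[, c("id", aa_alphabet(), "production_rate")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a variant dataset CSV
#'
#' @param path CSV written by [write_variants_csv()] (or any file with
#'   `id`, the 20 count columns, and `production_rate`).
#' @param low_cut,high_cut Thresholds used to derive labels.
#' @return Records data frame with a derived integer `label` column.
#' @export
read_variants_csv <- function(path, low_cut = 20, high_cut = 70) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_matrix(df)  # validates the count columns
  df$label <- categorize(df$production_rate, low_cut, high_cut)
  df
}
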