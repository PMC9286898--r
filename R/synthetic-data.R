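#' Configuration for the planted-rule synthetic world
#'
#' The generator emulates the three benchmark inputs — a compound descriptor
#' table, a disease symptom table and a labeled pair grid — with a planted
#' relationship rule so that every pipeline stage is testable without
#' external databases.  Compounds and diseases share a latent space of
#' dimension `n_latent`: compound descriptors are a dense linear mixing of
#' the compound's latent vector plus Gaussian noise (mimicking continuous
#' molecular descriptors), disease symptom vectors are a sparse non-negative
#' mixing of the disease's latent vector (one positive loading per symptom)
#' plus noise, clipped at zero (mimicking co-occurrence-derived symptom
#' weights).  The probability that a pair is related is
#' `plogis(signal_strength * <u_c, v_d> + offset)`, with the offset
#' calibrated so the expected positive fraction equals `positive_rate`;
#' labels are then drawn Bernoulli.  Disease latents are half-normal
#' (non-negative) so the signal survives the clipping of the symptom
#' vectors.
#'
#' Desk-scale defaults (64 compounds x 32 diseases, 64/32 descriptor
#' dimensions) keep encoding plus training in the minutes range; the
#' full-scale dimensions (5270/322) are reachable through the same
#' parameters.
#'
#' @param n_compounds,n_diseases entity counts.
#' @param d_compound,d_disease descriptor dimensions.
#' @param n_latent shared latent dimension.
#' @param signal_strength >= 0; 0 means labels are independent of the
#'   descriptors.
#' @param noise_sd Gaussian noise sd on compound descriptors (symptom noise
#'   is `0.3 * noise_sd`).
#' @param positive_rate expected fraction of positive pairs, in (0, 1).
#' @param qc_rate,blood_rate marginal rates of the QC / blood annotation
#'   flags.
#' @param seed integer seed; the whole world is reproducible from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_compounds = 64L, n_diseases = 32L,
                       d_compound = 64L, d_disease = 32L, n_latent = 4L,
                       signal_strength = 5, noise_sd = 0.5,
                       positive_rate = 0.5, qc_rate = 0.3, blood_rate = 0.3,
                       seed = 1L) {
  stopifnot(n_compounds >= 1, n_diseases >= 1, d_compound >= 1,
            d_disease >= 1, n_latent >= 1, signal_strength >= 0,
            noise_sd > 0, positive_rate > 0, positive_rate < 1,
            qc_rate >= 0, qc_rate <= 1, blood_rate >= 0, blood_rate <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_diseases = as.integer(n_diseases),
                 d_compound = as.integer(d_compound),
                 d_disease = as.integer(d_disease),
                 n_latent = as.integer(n_latent),
                 signal_strength = signal_strength, noise_sd = noise_sd,
                 positive_rate = positive_rate, qc_rate = qc_rate,
                 blood_rate = blood_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic compound-disease world
#'
#' @param config a [sim_config()].
#' @return a `cdr_world`: `compounds` and `diseases` (raw
#'   `descriptor_table`s), `pairs` (the full labeled grid with the
#'   ground-truth probability per pair), `truth` (latent vectors and the
#'   calibrated offset) and `config`.
#' @export
simulate_cdr_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nc <- config$n_compounds; nd <- config$n_diseases
    dc <- config$d_compound; dd <- config$d_disease
    k <- config$n_latent
    u <- matrix(stats::rnorm(nc * k), nc, k)
    v <- matrix(abs(stats::rnorm(nd * k)), nd, k)
    mixing <- matrix(stats::rnorm(k * dc), k, dc)
    comp_feat <- u %*% mixing +
      matrix(stats::rnorm(nc * dc, sd = config$noise_sd), nc, dc)
    colnames(comp_feat) <- sprintf("desc%04d", seq_len(dc))
    sym_latent <- sample.int(k, dd, replace = TRUE)
    sym_weight <- abs(stats::rnorm(dd))
    dis_feat <- v[, sym_latent, drop = FALSE] * rep(sym_weight, each = nd) +
      matrix(stats::rnorm(nd * dd, sd = 0.3 * config$noise_sd), nd, dd)
    dis_feat <- pmax(dis_feat, 0)
    colnames(dis_feat) <- sprintf("symp%04d", seq_len(dd))

    eta <- config$signal_strength * (u %*% t(v))
    f <- function(o) mean(stats::plogis(eta + o)) - config$positive_rate
    lo <- -abs(max(eta)) - 50; hi <- abs(min(eta)) + 50
    root <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10),
                     error = function(e) {
                       stop("cannot calibrate the positive rate to ",
                            config$positive_rate,
                            " at signal strength ", config$signal_strength)
                     })
    offset <- root$root
    true_prob <- stats::plogis(eta + offset)
    lab <- matrix(stats::rbinom(nc * nd, 1L, true_prob), nc, nd)

    cids <- sprintf("cmp%04d", seq_len(nc))
    dids <- sprintf("dis%04d", seq_len(nd))
    compounds <- descriptor_table(
      cids, comp_feat, "compound",
      is_qc = stats::runif(nc) < config$qc_rate,
      is_blood = stats::runif(nc) < config$blood_rate,
      ob_percent = round(stats::runif(nc, 0, 100), 2))
    diseases <- descriptor_table(dids, dis_feat, "disease")
    pairs <- data.frame(
      compound_id = rep(cids, nd),
      disease_id = rep(dids, each = nc),
      label = ifelse(as.vector(lab) == 1L, "positive", "negative"),
      true_prob = as.vector(true_prob),
      stringsAsFactors = FALSE)
    structure(list(compounds = compounds, diseases = diseases, pairs = pairs,
                   truth = list(u = u, v = v, offset = offset),
                   config = config),
              class = "cdr_world")
  })
}

#' @export
print.cdr_world <- function(x, ...) {
  cat("<cdr_world>", x$config$n_compounds, "compounds x",
      x$config$n_diseases, "diseases;",
      sum(x$pairs$label == "positive"), "positive pairs (rate",
      round(mean(x$pairs$label == "positive"), 3), ")\n")
  invisible(x)
}

#' Write a synthetic world as the three pipeline input files
#'
#' Produces `compounds.csv`, `diseases.csv` and `pairs.csv` in exactly the
#' dialect [read_descriptor_table()] and [read_pairs()] consume, plus
#' `truth.json` holding the generator configuration and ground-truth pair
#' probabilities.  The truth file is for auditing only; training code paths
#' read the three CSVs.
#'
#' @param world a `cdr_world`.
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
world_to_tables <- function(world, dir) {
  stopifnot(inherits(world, "cdr_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(compounds = file.path(dir, "compounds.csv"),
             diseases = file.path(dir, "diseases.csv"),
             pairs = file.path(dir, "pairs.csv"),
             truth = file.path(dir, "truth.json"))
  write_descriptor_table(world$compounds, paths["compounds"])
  write_descriptor_table(world$diseases, paths["diseases"])
  write_pairs(world$pairs[, c("compound_id", "disease_id", "label")],
              paths["pairs"])
  jsonlite::write_json(
    list(config = unclass(world$config),
         offset = world$truth$offset,
         true_prob = world$pairs$true_prob),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Encode a synthetic world for training
#'
#' Normalizes the compound and disease tables (per-feature min-max) and
#' encodes the requested pairs as a network-ready image stack.
#'
#' @param world a `cdr_world`.
#' @param pairs pairs to encode; defaults to the full grid.
#' @return list with `images` (a `cdr_image_stack`), `labels` (0/1 vector
#'   aligned with the stack) and `norm_params` for both tables.
#' @export
encode_world <- function(world, pairs = world$pairs) {
  comp <- normalize_descriptors(world$compounds)
  dis <- normalize_descriptors(world$diseases)
  stack <- encode_images(comp, dis, pairs)
  labels <- if ("label" %in% names(pairs)) {
    as.integer(pairs$label == "positive")
  } else NULL
  list(images = stack, labels = labels,
       norm_params = list(compound = comp$norm_params,
                          disease = dis$norm_params))
}
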