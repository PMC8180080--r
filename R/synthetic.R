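#' Configuration for the zero-inflated log-normal profile simulator
#'
#' The simulator models an untargeted GC-MS peak table as the product of a
#' Bernoulli detection indicator and a log-normal abundance, followed by a
#' hard censoring floor (\code{detection_limit}) standing in for the
#' instrument's peak-area cutoff. Background compounds are identically
#' distributed in both groups; planted markers get a log-scale abundance
#' shift and a high detection probability in cases but are nearly never
#' detected in controls; contaminants are high-detection compounds with
#' identical distribution in both groups and \code{is_contaminant = TRUE}.
#'
#' @param n_case,n_control sample counts per group.
#' @param m_compounds total number of compounds.
#' @param n_markers number of planted differential compounds.
#' @param n_contaminants number of planted contaminant compounds.
#' @param log_mu,log_sigma baseline log-normal parameters (natural-log scale).
#' @param marker_log_shift additive log-scale effect for planted markers in
#'   case samples, in units of natural-log abundance.
#' @param detect_p_case detection probability of a planted marker in cases.
#' @param detect_p_control_marker detection probability of a planted marker
#'   in controls (near zero: "nearly not detected" in controls).
#' @param detect_p_background detection probability of background compounds.
#' @param detect_p_contaminant detection probability of contaminants in both
#'   groups.
#' @param detection_limit abundance floor; values below it are censored to 0.
#' @param seed integer seed.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_case = 63, n_control = 61, m_compounds = 922,
                             n_markers = 8, n_contaminants = 8,
                             log_mu = log(10000), log_sigma = 1,
                             marker_log_shift = 3,
                             detect_p_case = 0.9,
                             detect_p_control_marker = 0.02,
                             detect_p_background = 0.5,
                             detect_p_contaminant = 0.95,
                             detection_limit = 700,
                             seed = 1L) {
  cfg <- list(n_case = n_case, n_control = n_control,
              m_compounds = m_compounds, n_markers = n_markers,
              n_contaminants = n_contaminants, log_mu = log_mu,
              log_sigma = log_sigma, marker_log_shift = marker_log_shift,
              detect_p_case = detect_p_case,
              detect_p_control_marker = detect_p_control_marker,
              detect_p_background = detect_p_background,
              detect_p_contaminant = detect_p_contaminant,
              detection_limit = detection_limit, seed = as.integer(seed))
  probs <- c(cfg$detect_p_case, cfg$detect_p_control_marker,
             cfg$detect_p_background, cfg$detect_p_contaminant)
  if (any(probs < 0) || any(probs > 1))
    stop("detection probabilities must be in [0, 1]")
  if (cfg$n_markers + cfg$n_contaminants > cfg$m_compounds)
    stop("n_markers + n_contaminants exceeds m_compounds")
  if (cfg$detection_limit < 0) stop("detection_limit must be >= 0")
  if (cfg$n_case < 1 || cfg$n_control < 1)
    stop("need at least one case and one control")
  if (cfg$log_sigma <= 0) stop("log_sigma must be positive")
  structure(cfg, class = "synthetic_config")
}

#' The study-shaped simulator preset
#'
#' Convenience preset matching the shape of the motivating study: 63 case
#' and 61 control samples, 922 compounds, 8 planted markers with a 3
#' log-sd abundance shift and near-total control dropout, and 8 planted
#' contaminants.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return A \code{synthetic_config}.
#' @export
paper_like_config <- function(...) synthetic_config(...)

#' Simulate a profile matrix with planted markers
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements \code{pm} (a \code{profile_matrix}),
#'   \code{planted_marker_ids} and \code{contaminant_ids}.
#' @examples
#' sim <- simulate_profile(synthetic_config(n_case = 10, n_control = 10,
#'                                          m_compounds = 50, n_markers = 2,
#'                                          n_contaminants = 1, seed = 7))
#' sim$planted_marker_ids
#' @export
simulate_profile <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  m <- cfg$m_compounds
  n <- cfg$n_case + cfg$n_control
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  is_case <- groups == "case"

  marker_idx <- seq_len(cfg$n_markers)
  contam_idx <- cfg$n_markers + seq_len(cfg$n_contaminants)
  kind <- rep("background", m)
  kind[marker_idx] <- "marker"
  kind[contam_idx] <- "contaminant"

  with_seed(cfg$seed, {
    # log-normal abundances; markers get the log shift in cases only
    mu <- matrix(cfg$log_mu, m, n)
    mu[marker_idx, is_case] <- cfg$log_mu + cfg$marker_log_shift
    abund <- matrix(exp(stats::rnorm(m * n, mean = mu, sd = cfg$log_sigma)),
                    m, n)
    # per-cell Bernoulli detection
    p <- matrix(cfg$detect_p_background, m, n)
    p[marker_idx, is_case] <- cfg$detect_p_case
    p[marker_idx, !is_case] <- cfg$detect_p_control_marker
    p[contam_idx, ] <- cfg$detect_p_contaminant
    detected <- matrix(stats::runif(m * n) < p, m, n)
  })
  abund[!detected] <- 0
  abund[abund < cfg$detection_limit] <- 0  # instrument censoring floor

  pad <- function(i) formatC(i, width = nchar(m), flag = "0")
  compound_id <- paste0("cpd_", pad(seq_len(m)))
  name <- ifelse(kind == "contaminant",
                 paste0("Siloxane-like background ", pad(seq_len(m))),
                 paste0("Compound ", pad(seq_len(m)), " (TMS)"))
  compounds <- data.frame(
    compound_id = compound_id, name = name,
    mass = 73L + (seq_len(m) %% 400L),
    metabolite = ifelse(kind == "marker",
                        paste0("metabolite_", pad(seq_len(m))), "unknown"),
    is_contaminant = kind == "contaminant",
    stringsAsFactors = FALSE)

  pm <- profile_matrix(abund, compounds,
                       sample_ids = sprintf("%s_%02d",
                                            ifelse(is_case, "BC", "HE"),
                                            c(seq_len(cfg$n_case),
                                              seq_len(cfg$n_control))),
                       groups = groups)
  list(pm = pm,
       planted_marker_ids = compound_id[marker_idx],
       contaminant_ids = compound_id[contam_idx])
}
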