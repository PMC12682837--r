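#' Build a simulation-ready parameter set for a treatment
#'
#' In \code{tabulated} mode the packaged per-treatment tables are used
#' verbatim. In \code{response-driven} mode the treatment-averaged
#' "general" root parameter set is modified by the fitted P-response
#' functions at the treatment's soil P level (scheduling and shoot rows
#' still come from the treatment's own table).
#'
#' @param treatment "P0", "P1", "P2" or "P3".
#' @param mode "tabulated" or "response-driven".
#' @param model optional \code{p_response_model}; fitted from the
#'   packaged tables when NULL (response-driven mode only).
#' @param DM named dry-matter vector (g) for forming PB.
#' @return a \code{plant_params} object.
#' @export
build_treatment <- function(treatment,
                            mode = c("tabulated", "response-driven"),
                            model = NULL, DM = default_dry_matter()) {
  mode <- match.arg(mode)
  tab <- load_parameter_table(treatment)
  if (mode == "tabulated") {
    return(plant_params(tab))
  }
  if (is.null(model)) model <- fit_p_response(DM = DM)
  base <- load_parameter_table("general")
  P <- soil_p_levels()[[treatment]]
  responded <- apply_response(base, P, DM_plant = DM[[treatment]],
                              model = model)
  responded$treatment <- treatment
  pp <- plant_params(responded, base = tab)
  # leaf elongation response lives in the shoot table, not the root table
  pp$shoot$leaf$r[["mean"]] <- leaf_elongation_response(P, model$leaf)
  pp
}

#' Run a K_rs simulation ensemble
#'
#' Repeats simulate -> solve -> K_rs over n seeds derived as
#' \code{base_seed + 0:(n-1)}, evaluating K_rs at each query time, and
#' attaches per-seed architecture summaries at the final time.
#'
#' @param params a \code{plant_params} object.
#' @param n ensemble size (>= 1).
#' @param base_seed first seed; replicate i uses base_seed + i - 1.
#' @param times K_rs evaluation times (days after sowing).
#' @param profile a \code{hydraulic_profile} (default: packaged synthetic
#'   stand-in).
#' @param psi_sr uniform soil water potential (cm head); K_rs does not
#'   depend on it.
#' @param psi_collar collar potential (cm head); K_rs does not depend on
#'   it either.
#' @return object of class \code{ensemble_result}: list with
#'   \code{treatment}, \code{seeds}, \code{krs} (data.frame seed, t,
#'   krs), \code{summary} (mean/s.d./s.e. per time) and
#'   \code{architecture} (per-seed totals at max(times)).
#' @export
run_ensemble <- function(params, n = 100, base_seed = 1L,
                         times = c(7, 14, 21, 28),
                         profile = default_hydraulic_profile(),
                         psi_sr = -300, psi_collar = -1000) {
  stopifnot(inherits(params, "plant_params"), n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  krs_rows <- vector("list", n)
  arch_rows <- vector("list", n)
  for (i in seq_len(n)) {
    net <- simulate_plant(params, t_end = max(times), seed = seeds[i])
    ts <- krs_time_series(net, profile, times, psi_sr, psi_collar)
    krs_rows[[i]] <- cbind(seed = seeds[i], ts)
    sm <- summarize_network(net, roots_only = TRUE)
    arch_rows[[i]] <- data.frame(seed = seeds[i],
                                 total_length = sum(sm$length),
                                 total_surface = sum(sm$surface),
                                 total_volume = sum(sm$volume),
                                 n_crown = sum(net$schedule$type == "crown"))
  }
  krs <- do.call(rbind, krs_rows)
  agg <- do.call(rbind, lapply(split(krs, krs$t), function(d) {
    data.frame(t = d$t[1], mean_krs = mean(d$krs), sd_krs = stats::sd(d$krs),
               se_krs = stats::sd(d$krs) / sqrt(nrow(d)), n = nrow(d))
  }))
  rownames(agg) <- NULL
  structure(list(treatment = params$treatment, seeds = seeds, krs = krs,
                 summary = agg, architecture = do.call(rbind, arch_rows)),
            class = "ensemble_result")
}

#' Summary table across treatment ensembles
#'
#' @param results named list of \code{ensemble_result} objects (one per
#'   treatment).
#' @param welch also run pairwise Welch t-tests on K_rs at the latest
#'   time (descriptive only).
#' @return data.frame treatment x time with mean, s.d., s.e. of K_rs;
#'   with attribute \code{welch} when requested.
#' @export
summarize_experiment <- function(results, welch = FALSE) {
  tab <- do.call(rbind, lapply(results, function(res) {
    cbind(treatment = res$treatment, res$summary)
  }))
  rownames(tab) <- NULL
  if (welch && length(results) >= 2) {
    tmax <- max(tab$t)
    prs <- utils::combn(seq_along(results), 2)
    w <- apply(prs, 2, function(ij) {
      a <- results[[ij[1]]]; b <- results[[ij[2]]]
      tt <- stats::t.test(a$krs$krs[a$krs$t == tmax],
                          b$krs$krs[b$krs$t == tmax])
      data.frame(a = a$treatment, b = b$treatment,
                 t = tmax, p_value = tt$p.value)
    })
    attr(tab, "welch") <- do.call(rbind, w)
  }
  tab
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result (%s): n = %d seeds\n",
              x$treatment, length(x$seeds)))
  print(x$summary)
  invisible(x)
}
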