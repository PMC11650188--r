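# End-to-end orchestration: simulate or load -> harmonize -> normative ->
# factorize -> stats -> network / molecular -> subtype, with every
# intermediate written as delimited text and a checksummed manifest.

default_pipeline_config <- function() {
  list(
    seed = 1,
    simulate = list(n_hc = 200, n_patients = 200, n_regions = 60,
                    n_sites = 3, k_pos = 2, k_neg = 2, n_subtypes = 4,
                    noise_sd = 0.5),
    harmonize = list(covariates = c("age", "sex", "group")),
    normative = list(restarts = 3, maxit = 100),
    factors = list(k_range = 2:6, n_repeats = 20),
    n_perm = 200,
    subtype = list(candidate_range = 2:10),
    skip = character(),
    out_dir = NULL
  )
}

#' Run the full differential-factor pipeline
#'
#' Executes every stage against a synthetic bundle (default) or supplied
#' tables: site harmonization, normative modeling and deviation scoring,
#' signed split with split-half rank selection and NMF per bank,
#' group-difference map and factor association, clinical correlation,
#' structural-covariance epicenter mapping, receptor dominance and gene
#' expression correlation, and subtyping. All artifacts are written as
#' TSV/JSON under `out_dir` and listed, with MD5 checksums, in
#' `manifest.json`.
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults: `seed`, `simulate` (generator parameters), `harmonize`,
#'   `normative`, `factors` (`k_range`, `n_repeats`), `n_perm`,
#'   `subtype`, `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the fitted objects and the manifest
#'   tibble (`artifact`, `file`, `md5`, `status`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("devfactor_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  manifest <- list()
  emit <- function(name, obj, writer = write_tsv_artifact) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest[[length(manifest) + 1L]] <<- tibble(
      artifact = name, file = path,
      md5 = unname(tools::md5sum(path)), status = "written"
    )
    invisible(path)
  }
  skip <- function(name) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      artifact = name, file = NA_character_, md5 = NA_character_,
      status = "skipped"
    )
  }

  message("stage: data")
  bundle <- do.call(generate_cohort,
                    c(cfg$simulate, list(seed = child_seed(seed, "simulate"))))

  message("stage: harmonize")
  pooled <- dplyr::bind_rows(bundle$hc, bundle$patients)
  harm <- combat_fit_transform(pooled, batch = "site",
                               covariates = cfg$harmonize$covariates)
  hc_h <- harm$harmonized[harm$harmonized$group == "hc", , drop = FALSE]
  pat_h <- harm$harmonized[harm$harmonized$group == "patient", , drop = FALSE]
  emit("hc_harmonized.tsv", hc_h)
  emit("patients_harmonized.tsv", pat_h)

  message("stage: normative")
  nm <- fit_normative(hc_h, restarts = cfg$normative$restarts,
                      maxit = cfg$normative$maxit)
  z <- deviation_scores(nm, pat_h)
  overlap <- extreme_deviation_overlap(z)
  emit("zscores.tsv", z)
  emit("extreme_overlap.tsv", overlap)

  message("stage: factors")
  sp <- split_signed(z)
  sel_pos <- select_k(sp$pos, k_range = cfg$factors$k_range,
                      n_repeats = cfg$factors$n_repeats,
                      seed = child_seed(seed, "k_pos"))
  sel_neg <- select_k(sp$neg, k_range = cfg$factors$k_range,
                      n_repeats = cfg$factors$n_repeats,
                      seed = child_seed(seed, "k_neg"))
  fm_pos <- fit_nmf(sp$pos, sel_pos$k_best, seed = child_seed(seed, "nmf_pos"))
  fm_neg <- fit_nmf(sp$neg, sel_neg$k_best, seed = child_seed(seed, "nmf_neg"))
  emit("ge_pos.tsv", sel_pos$ge)
  emit("ge_neg.tsv", sel_neg$ge)
  emit("factors_pos.tsv", loadings_tibble(fm_pos))
  emit("factors_neg.tsv", loadings_tibble(fm_neg))
  W <- combined_weights(fm_pos, fm_neg, z$subject_id)
  emit("weights.tsv", W)
  ve <- variance_explained(z, fm_pos, fm_neg)
  emit("variance_explained.tsv", ve)

  message("stage: group statistics")
  gm <- group_difference_map(pat_h, hc_h)
  emit("group_map.tsv", gm)
  fx <- factors_explain_map(gm, signed_factor_maps(fm_pos, fm_neg),
                            n_perm = cfg$n_perm,
                            seed = child_seed(seed, "explain"))
  emit("factors_explain_map.json", fx, write_json_artifact)
  wmat <- as.matrix(W[, -1, drop = FALSE])
  clin <- composition_association(wmat, pat_h, type = "correlation",
                                  score_var = "hamd")
  emit("clinical_correlation.tsv", clin)

  message("stage: network")
  if (!("network" %in% cfg$skip) && !is.null(bundle$gmv)) {
    sc <- build_sc_network(bundle$gmv)
    emit("sc_network.tsv", sc, write_matrix_artifact)
    ep <- epicenter_ranking(fm_pos$F[1, ], sc, n_perm = cfg$n_perm,
                            seed = child_seed(seed, "epicenter"))
    emit("epicenter_pos1.tsv", ep)
  } else {
    skip("sc_network.tsv"); skip("epicenter_pos1.tsv")
  }

  message("stage: molecular")
  skip_molecular <- "molecular" %in% cfg$skip
  if (!skip_molecular && !is.null(bundle$receptors)) {
    maps <- signed_factor_maps(fm_pos, fm_neg)
    map_list <- setNames(
      lapply(seq_len(nrow(maps)), function(i) abs(maps[i, ])),
      rownames(maps)
    )
    rm_res <- receptor_model(map_list, bundle$receptors,
                             n_perm = cfg$n_perm,
                             seed = child_seed(seed, "receptor"))
    emit("receptor_models.tsv", rm_res)
    dom <- dominance_analysis(fm_pos$F[1, ], bundle$receptors)
    emit("dominance_pos1.tsv", dom$dominance)
  } else {
    skip("receptor_models.tsv"); skip("dominance_pos1.tsv")
  }
  if (!skip_molecular && !is.null(bundle$expression)) {
    ev <- build_expression_vector(bundle$expression)
    ec <- expression_correlation(fm_pos$F[1, ], ev, n_perm = cfg$n_perm,
                                 seed = child_seed(seed, "expression"))
    emit("expression_correlation.json", ec, write_json_artifact)
  } else {
    skip("expression_correlation.json")
  }

  message("stage: subtyping")
  sm <- fit_subtypes(wmat, candidate_range = cfg$subtype$candidate_range,
                     seed = child_seed(seed, "subtype"))
  emit("subtype_bic.tsv", sm$bic)
  emit("subtype_labels.tsv",
       tibble(subject_id = W$subject_id, subtype = sm$labels))
  prof <- subtype_profiles(pat_h, hc_h, sm$labels)
  emit("subtype_clinical.tsv", prof$clinical)

  manifest_tbl <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest_tbl, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  message(sprintf("pipeline complete: %d artifacts in %s",
                  sum(manifest_tbl$status == "written"), out_dir))
  invisible(list(
    bundle = bundle, normative = nm, z = z,
    factors = list(pos = fm_pos, neg = fm_neg,
                   select_pos = sel_pos, select_neg = sel_neg),
    group_map = gm, explain = fx, subtypes = sm,
    manifest = manifest_tbl, out_dir = out_dir
  ))
}

loadings_tibble <- function(fm) {
  dplyr::bind_cols(tibble(factor = rownames(fm$F)), as_tibble(fm$F))
}

combined_weights <- function(fm_pos, fm_neg, ids) {
  wp <- fm_pos$W; colnames(wp) <- paste0("pos_", seq_len(ncol(wp)))
  wn <- fm_neg$W; colnames(wn) <- paste0("neg_", seq_len(ncol(wn)))
  dplyr::bind_cols(tibble(subject_id = ids), as_tibble(cbind(wp, wn)))
}

write_tsv_artifact <- function(obj, path) {
  write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write_matrix_artifact <- function(obj, path) {
  m <- as.data.frame(unclass(obj))
  write.table(cbind(region = rownames(unclass(obj)), m), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}
write_json_artifact <- function(obj, path) {
  if (inherits(obj, "association_result")) obj <- unclass(obj)
  obj$null <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
}
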