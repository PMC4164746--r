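#' Simulate the puncta fields of one section
#'
#' Builds the per-channel ground truth for one two-channel section of one
#' animal: lamina I and lamina II of both dorsal horns are populated by
#' homogeneous Poisson puncta fields whose densities are the sham baseline
#' scaled by the configured percent-of-sham for the animal's group, by the
#' animal's multiplicative random effect, and by a section-level effect.
#' Lamina-II scaling applies within the (mirrored) lesion-zone medio-lateral
#' interval only — outside it lamina II stays at the animal's baseline —
#' while lamina-I scaling applies across the band.
#'
#' @param geometry a [generate_geometry()] object.
#' @param config a [timecourse_config()] object.
#' @param day,group condition simulated.
#' @param animal_factors named per-marker multiplicative animal effects
#'   (from the shared-coupling model; see [simulate_cohort()]).
#' @param seed integer seed for this section.
#' @return list with `fields` (named list of combined puncta tibbles per
#'   channel) and `truth` (tibble per side x lamina x marker with
#'   `true_density` — the realised density in the quantification region,
#'   i.e. the lesion interval for LII and the band for LI — and
#'   `true_count`).
#' @export
simulate_section_fields <- function(geometry, config, day, group,
                                    animal_factors = c(IB4 = 1, GAD65 = 1),
                                    seed = 1L) {
  stopifnot(inherits(geometry, "dh_geometry"), inherits(config, "dh_timecourse"))
  lesion <- geometry$lesion_zone
  markers <- names(config$baseline_density)
  fields <- stats::setNames(vector("list", length(markers)), markers)
  truth <- list()
  for (mi in seq_along(markers)) {
    m <- markers[mi]
    sec_factor <- withr_seed(derive_seed(seed, 3L, mi),
                             rlnorm_mean_cv(1, 1, config$section_cv))
    parts <- list()
    for (side in c("ipsilateral", "contralateral")) {
      s_i <- match(side, c("ipsilateral", "contralateral"))
      mod <- animal_factors[[m]] * sec_factor
      # lamina I: whole band at the configured percentage
      li_rect <- lamina_rect(geometry, "LI", side)
      li_pct <- lookup_pct(config, day, group, side, "LI", m)
      li_dens <- config$baseline_density[[m]][["LI"]] * li_pct / 100 * mod
      li_field <- sample_puncta(li_rect, li_dens, config$mean_area_um2[[m]],
                                config$area_cv, channel = m,
                                seed = derive_seed(seed, 5L, mi, s_i, 1L))
      # lamina II: lesion interval at the configured percentage, flanks at
      # the animal's baseline
      lii_rect <- lamina_rect(geometry, "LII", side)
      lx <- c(lesion[["x0"]], lesion[["x1"]])
      if (side == "contralateral") lx <- sort(mirror_x(geometry, lx))
      lesion_rect <- c(x0 = lx[1], x1 = lx[2],
                       y0 = lii_rect[["y0"]], y1 = lii_rect[["y1"]])
      lii_pct <- lookup_pct(config, day, group, side, "LII", m)
      base_lii <- config$baseline_density[[m]][["LII"]] * mod
      lesion_dens <- base_lii * lii_pct / 100
      lesion_field <- sample_puncta(lesion_rect, lesion_dens,
                                    config$mean_area_um2[[m]], config$area_cv,
                                    channel = m,
                                    seed = derive_seed(seed, 5L, mi, s_i, 2L))
      flanks <- list(
        c(x0 = lii_rect[["x0"]], x1 = lx[1],
          y0 = lii_rect[["y0"]], y1 = lii_rect[["y1"]]),
        c(x0 = lx[2], x1 = lii_rect[["x1"]],
          y0 = lii_rect[["y0"]], y1 = lii_rect[["y1"]])
      )
      flank_fields <- purrr::imap(flanks, function(r, fi) {
        if (r[["x1"]] <= r[["x0"]]) return(NULL)
        sample_puncta(r, base_lii, config$mean_area_um2[[m]], config$area_cv,
                      channel = m,
                      seed = derive_seed(seed, 5L, mi, s_i, 2L + fi))
      })
      parts[[side]] <- dplyr::bind_rows(li_field, lesion_field,
                                        purrr::compact(flank_fields))
      truth[[paste(m, side)]] <- tibble::tibble(
        side = side, lamina = c("LI", "LII"), marker = m,
        true_density = c(li_dens, lesion_dens),
        true_count = c(nrow(li_field), nrow(lesion_field)),
        region_area_um2 = c(rect_area(li_rect), rect_area(lesion_rect))
      )
    }
    fields[[m]] <- dplyr::bind_rows(parts)
  }
  list(fields = fields, truth = dplyr::bind_rows(truth))
}

# per-animal multiplicative effects with a shared latent factor coupling the
# two markers: log-effects are sd_a * (sqrt(c) z_shared + sqrt(1-c) z_m),
# mean-one on the natural scale
animal_effects <- function(config, markers, seed) {
  sd_a <- sqrt(log(1 + config$animal_cv^2))
  withr_seed(seed, {
    z_shared <- stats::rnorm(1)
    z_m <- stats::rnorm(length(markers))
  })
  z <- sqrt(config$coupling) * z_shared + sqrt(1 - config$coupling) * z_m
  stats::setNames(exp(sd_a * z - sd_a^2 / 2), markers)
}

#' Simulate and quantify one day's histology cohort in memory
#'
#' Streams the full pipeline for one post-surgery day: for every animal and
#' section, sample ground-truth puncta fields, render the two-channel
#' micrograph, and quantify it (lesion detection, ROI placement, counting),
#' discarding each image after quantification so memory stays flat. This is
#' the parameter-recovery entry point; [simulate_cohort()] is the
#' file-writing equivalent.
#'
#' @param config a [timecourse_config()] object.
#' @param day post-surgery day.
#' @param seed cohort seed; animal and section sub-seeds derive from it.
#' @param geometry section geometry (shared across sections).
#' @param noise a [noise_model()].
#' @param params a [quant_params()] list.
#' @param progress print one line per animal.
#' @return tibble of density records: one row per
#'   section x side x lamina x marker with `animal`, `group`, `day`,
#'   `section`, the [quantify_section()] columns, and the section truth
#'   (`true_density`, `true_count`) joined in.
#' @export
simulate_quantify_day <- function(config, day, seed = 1L,
                                  geometry = generate_geometry(),
                                  noise = noise_model(),
                                  params = quant_params(),
                                  progress = FALSE) {
  stopifnot(inherits(config, "dh_timecourse"), day %in% config$days)
  groups <- c(rep("sham", config$sham_n), rep("cuff", config$cuff_n))
  animals <- sprintf("%s_%02d", groups,
                     c(seq_len(config$sham_n), seq_len(config$cuff_n)))
  markers <- names(config$baseline_density)
  day_i <- match(day, config$days)
  out <- list()
  for (a in seq_along(animals)) {
    if (progress) message("animal ", animals[a], " (day ", day, ")")
    af <- animal_effects(config, markers, derive_seed(seed, day_i, a, 1L))
    for (s in seq_len(config$sections_per_animal)) {
      sec_seed <- derive_seed(seed, day_i, a, 100L + s)
      sim <- simulate_section_fields(geometry, config, day, groups[a],
                                     af, seed = sec_seed)
      mg <- render_micrograph(geometry, sim$fields, noise,
                              seed = derive_seed(seed, day_i, a, 200L + s))
      rec <- quantify_section(mg, geometry, params)
      rec <- dplyr::left_join(rec, sim$truth,
                              by = c("side", "lamina", "marker"))
      rec$animal <- animals[a]
      rec$group <- groups[a]
      rec$day <- day
      rec$section <- s
      out[[length(out) + 1]] <- rec
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a full synthetic dataset on disk
#'
#' Writes, for each requested day, animal and section, a two-page 16-bit
#' TIFF (one page per channel, holding 12-bit data), a YAML sidecar with the
#' pixel size, channel names and geometry, and a per-image puncta CSV; plus
#' a ground-truth manifest CSV linking every image to its condition and true
#' densities, behavioural trial CSVs, and the effective configuration as
#' YAML.
#'
#' @inheritParams simulate_quantify_day
#' @param out_dir output directory (created if missing).
#' @param days days to simulate (default: all configured days).
#' @param behavior also simulate the behavioural cohort per day.
#' @return (invisibly) the manifest tibble; files under `out_dir`:
#'   `images/*.tif{,.yaml}`, `puncta/*.csv`, `manifest.csv`,
#'   `vf_trials.csv`, `hg_trials.csv`, `config.yaml`.
#' @export
simulate_cohort <- function(config, seed = 1L, out_dir,
                            days = config$days,
                            geometry = generate_geometry(),
                            noise = noise_model(),
                            behavior = TRUE,
                            progress = FALSE) {
  stopifnot(inherits(config, "dh_timecourse"), all(days %in% config$days))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "puncta"), showWarnings = FALSE)
  groups <- c(rep("sham", config$sham_n), rep("cuff", config$cuff_n))
  animals <- sprintf("%s_%02d", groups,
                     c(seq_len(config$sham_n), seq_len(config$cuff_n)))
  markers <- names(config$baseline_density)
  manifest <- list(); vf_all <- list(); hg_all <- list()
  for (day in days) {
    day_i <- match(day, config$days)
    for (a in seq_along(animals)) {
      if (progress) message("day ", day, " animal ", animals[a])
      af <- animal_effects(config, markers, derive_seed(seed, day_i, a, 1L))
      for (s in seq_len(config$sections_per_animal)) {
        sec_seed <- derive_seed(seed, day_i, a, 100L + s)
        sim <- simulate_section_fields(geometry, config, day, groups[a],
                                       af, seed = sec_seed)
        mg <- render_micrograph(geometry, sim$fields, noise,
                                seed = derive_seed(seed, day_i, a, 200L + s))
        stem <- sprintf("d%02d_%s_s%d", day, animals[a], s)
        img_path <- file.path(out_dir, "images", paste0(stem, ".tif"))
        write_micrograph(mg, img_path)
        puncta <- dplyr::bind_rows(mg_fields_table(sim$fields))
        utils::write.csv(puncta, file.path(out_dir, "puncta",
                                           paste0(stem, ".csv")),
                         row.names = FALSE)
        mrow <- sim$truth
        mrow$image <- file.path("images", paste0(stem, ".tif"))
        mrow$animal <- animals[a]; mrow$group <- groups[a]
        mrow$day <- day; mrow$section <- s
        manifest[[length(manifest) + 1]] <- mrow
      }
    }
    if (behavior) {
      beh <- simulate_behavior_cohort(config, day,
                                      seed = derive_seed(seed, day_i, 999L))
      vf_all[[length(vf_all) + 1]] <- dplyr::mutate(beh$vf_trials, day = day)
      hg_all[[length(hg_all) + 1]] <- dplyr::mutate(beh$hg_trials, day = day)
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest$schema_version <- 1L
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  if (behavior) {
    utils::write.csv(dplyr::bind_rows(vf_all),
                     file.path(out_dir, "vf_trials.csv"), row.names = FALSE)
    utils::write.csv(dplyr::bind_rows(hg_all),
                     file.path(out_dir, "hg_trials.csv"), row.names = FALSE)
  }
  write_run_config(list(seed = seed, days = days, geometry = geometry_params(geometry),
                        noise = unclass(noise)[setdiff(names(unclass(noise)), "")],
                        cohort = list(sham_n = config$sham_n, cuff_n = config$cuff_n,
                                      behavior_n = config$behavior_n,
                                      sections_per_animal = config$sections_per_animal)),
                   file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

mg_fields_table <- function(fields) {
  purrr::map(fields, function(f) {
    tibble::tibble(x_um = f$x_um, y_um = f$y_um, area_um2 = f$area_um2,
                   intensity = f$amplitude, channel = f$channel)
  })
}
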