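#' Write / read a synthetic scene
#'
#' The image is written as 8-bit grayscale PNG, the mask as 0/255 PNG, and
#' the ground-truth gland parameters as a JSON sidecar next to the image.
#'
#' @param scene an `eyelid_scene`.
#' @param image_path,mask_path,json_path output paths; defaults derive the
#'   mask and sidecar names from `image_path`.
#' @return Invisibly, the three paths.
#' @export
write_scene <- function(scene, image_path,
                        mask_path = sub("\\.png$", "_mask.png", image_path),
                        json_path = sub("\\.png$", ".json", image_path)) {
  stopifnot(inherits(scene, "eyelid_scene"))
  png::writePNG(scene$image, image_path)
  png::writePNG(scene$mask * 1.0, mask_path)
  jsonlite::write_json(
    list(gland_params = lapply(scene$gland_params, unclass),
         canvas = dim(scene$mask)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = image_path, mask = mask_path, json = json_path))
}

#' @rdname write_scene
#' @return `read_scene` returns a list with `image`, `mask` (0/1 integer) and
#'   `gland_params`.
#' @export
read_scene <- function(image_path,
                       mask_path = sub("\\.png$", "_mask.png", image_path),
                       json_path = sub("\\.png$", ".json", image_path)) {
  image <- png::readPNG(image_path)
  mask <- png::readPNG(mask_path)
  mask <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
  params <- NULL
  if (file.exists(json_path)) {
    js <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    params <- lapply(seq_len(nrow(js$gland_params)), function(i) {
      p <- as.list(js$gland_params[i, ])
      do.call(gland_shape_params, p)
    })
  }
  list(image = image, mask = mask, gland_params = params)
}

#' Write a rendered cohort to disk
#'
#' Writes every rendered eye's image/mask/sidecar under `dir` and a CSV
#' manifest (`manifest.csv`: subject_id, laterality, group, image_path,
#' mask_path) plus the true per-gland deformation values
#' (`true_values.csv`).
#'
#' @param cohort a rendered cohort from [generate_cohort()] (with scenes).
#' @param dir output directory, created if needed.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$scenes))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(cohort$scenes), function(nm) {
    sc <- cohort$scenes[[nm]]
    ip <- file.path(dir, paste0(nm, ".png"))
    write_scene(sc$scene, ip)
    data.frame(subject_id = sc$subject_id, laterality = sc$laterality,
               group = sc$group, image_path = paste0(nm, ".png"),
               mask_path = paste0(nm, "_mask.png"), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$values, file.path(dir, "true_values.csv"),
            row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Analyze every eye of a cohort manifest
#'
#' Runs [analyze_eye()] on each mask listed in a cohort manifest (or on the
#' in-memory scenes of a rendered cohort) and returns the long per-gland
#' table consumed by [emit_tables()].
#'
#' @param cohort either a rendered cohort from [generate_cohort()] or a
#'   directory containing `manifest.csv` as written by [write_cohort()].
#' @param ... passed to [analyze_eye()].
#' @return data.frame: subject_id, laterality, group, gland_index, pa, pb,
#'   L_central, w_avg, sigma_w, n, D.
#' @export
analyze_cohort <- function(cohort, ...) {
  eyes <- if (is.character(cohort)) {
    manifest <- read.csv(file.path(cohort, "manifest.csv"),
                         stringsAsFactors = FALSE)
    lapply(seq_len(nrow(manifest)), function(i) {
      m <- manifest[i, ]
      sc <- read_scene(file.path(cohort, m$image_path),
                       file.path(cohort, m$mask_path))
      list(mask = sc$mask, subject_id = m$subject_id,
           laterality = m$laterality, group = m$group)
    })
  } else {
    stopifnot(!is.null(cohort$scenes))
    lapply(cohort$scenes, function(sc)
      list(mask = sc$scene$mask, subject_id = sc$subject_id,
           laterality = sc$laterality, group = sc$group))
  }
  do.call(rbind, lapply(eyes, function(e) {
    rec <- analyze_eye(e$mask, laterality = e$laterality, group = e$group,
                       subject_id = e$subject_id, ...)
    cbind(data.frame(subject_id = e$subject_id, laterality = e$laterality,
                     group = e$group, stringsAsFactors = FALSE),
          as.data.frame(rec))
  }))
}

#' Bundled published clinical summary tables
#'
#' Loads the transcribed summary rows of the published deformation-
#' coefficient tables shipped with the package: the per-gland paired
#' differences between treated and control eyes (mean, SD, SE, 95% CI, t, p),
#' and the per-site summaries of each group (mean, SD, 95% CI) together with
#' the printed ANOVA F, p and LSD ordering. These printed rows are the input
#' for the summary-arithmetic reproduction utilities ([t_from_summary()],
#' [ci_from_summary()], [anova_from_summary()], [infer_n_from_summary()]).
#'
#' @return List: `paired`, `treatment_sites`, `control_sites` (data.frames),
#'   `meta` (per-group printed F, p and LSD strings).
#' @export
gland_summary_tables <- function() {
  f <- function(name) read.csv(
    system.file("extdata", name, package = "meibomorph", mustWork = TRUE),
    stringsAsFactors = FALSE, comment.char = "#")
  list(paired = f("published_paired_differences.csv"),
       treatment_sites = f("published_sites_treatment.csv"),
       control_sites = f("published_sites_control.csv"),
       meta = f("published_anova_meta.csv"))
}

#' Write cohort tables as CSV files
#'
#' @param tables a `cohort_tables` object from [emit_tables()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "cohort_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "paired_differences.csv"),
             file.path(dir, "sites_treatment.csv"),
             file.path(dir, "sites_control.csv"),
             file.path(dir, "meta.json"))
  write.csv(tables$paired, paths[1], row.names = FALSE)
  add_anova <- function(tab, grp) {
    an <- tables$anova[[grp]]
    tab$F <- if (is.null(an)) NA_real_ else an$F
    tab$p_anova <- if (is.null(an)) NA_real_ else an$p
    tab$lsd <- if (is.null(tables$lsd[[grp]])) NA_character_
    else tables$lsd[[grp]]$ordering
    tab
  }
  write.csv(add_anova(tables$treatment_sites, "treatment"), paths[2],
            row.names = FALSE)
  write.csv(add_anova(tables$control_sites, "control"), paths[3],
            row.names = FALSE)
  jsonlite::write_json(tables$meta, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
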