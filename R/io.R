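# Readers and writers: PTS landmark files, PNG images, the manifest, the
# long-format rating and personality CSVs and the component-score matrix
# layout (participants in columns). Loaders validate and reject rather
# than coerce.

#' Read / write a PTS landmark file
#'
#' The PTS dialect: a `version:` line, an `n_points:` line, then the
#' points as `x y` lines between `{` and `}`.
#'
#' @param path file path.
#' @return `read_pts` returns a landmark shape matrix; `write_pts` the
#'   path, invisibly.
#' @export
read_pts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  np_line <- grep("^n_points:", lines, value = TRUE)
  if (!length(np_line)) stop("not a PTS file (missing n_points): ", path)
  n <- as.integer(sub("^n_points:\\s*", "", np_line[1]))
  open <- which(lines == "{"); close <- which(lines == "}")
  if (!length(open) || !length(close)) stop("malformed PTS file: ", path)
  body <- lines[(open[1] + 1):(close[1] - 1)]
  body <- body[nzchar(body)]
  if (length(body) != n) stop("PTS point count mismatch in ", path)
  coords <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  if (anyNA(coords) || ncol(coords) != 2L)
    stop("non-numeric PTS coordinates in ", path)
  as_landmark_shape(coords)
}

#' @rdname read_pts
#' @param shape landmark matrix to write.
#' @export
write_pts <- function(shape, path) {
  shape <- as_landmark_shape(shape)
  writeLines(c("version: 1",
               sprintf("n_points: %d", nrow(shape)),
               "{",
               sprintf("%.6f %.6f", shape[, 1], shape[, 2]),
               "}"), path)
  invisible(path)
}

#' Read / write a face image as PNG
#'
#' Grayscale matrices are written as 8-bit gray PNG; height x width x 3
#' arrays as RGB. Reading an RGB(A) file with `gray = TRUE` averages the
#' colour channels.
#'
#' @param path file path.
#' @param gray collapse colour to grayscale on read (default TRUE).
#' @return `read_face_png`: matrix (or array) of intensities in 0..1.
#' @export
read_face_png <- function(path, gray = TRUE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && gray) {
    img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' @rdname read_face_png
#' @param image matrix or array in 0..1.
#' @export
write_face_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Load a cohort manifest
#'
#' @param path CSV with columns `ratee_id`, `gender`, `image`, `landmarks`
#'   (paths relative to the manifest's directory).
#' @param check_files verify the referenced files exist (default TRUE).
#' @return the manifest data.frame with paths made absolute.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ratee_id", "gender", "image", "landmarks")
  if (!all(need %in% names(m)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(m$ratee_id)) stop("duplicate ratee ids in manifest")
  base <- dirname(normalizePath(path))
  m$image <- file.path(base, m$image)
  m$landmarks <- file.path(base, m$landmarks)
  if (check_files) {
    missing <- c(m$image[!file.exists(m$image)],
                 m$landmarks[!file.exists(m$landmarks)])
    if (length(missing))
      stop("missing files referenced by manifest: ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  m
}

#' Load a long-format ratings CSV
#'
#' Columns `judge_id`, `ratee_id`, `trait`, `score`; traits are validated
#' against the canonical 12-name vocabulary and scores against the integer
#' 1-9 Likert range. Invalid rows are rejected with their row numbers, not
#' coerced.
#'
#' @param path CSV path.
#' @return validated rating data.frame.
#' @export
load_ratings_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("judge_id", "ratee_id", "trait", "score")
  if (!all(need %in% names(tab)))
    stop("ratings CSV needs columns ", paste(need, collapse = ", "))
  tab$judge_id <- as.character(tab$judge_id)
  tab$ratee_id <- as.character(tab$ratee_id)
  validate_rating_table(tab)
  tab
}

#' @rdname load_ratings_csv
#' @param table rating data.frame to write.
#' @export
write_ratings_csv <- function(table, path) {
  validate_rating_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Load a personality CSV (long or wide)
#'
#' Long format has columns `ratee_id`, `trait`, `score`; wide format has
#' `ratee_id` plus one column per trait. Scores must lie in 1-10.
#'
#' @param path CSV path.
#' @return ratee x trait matrix with ratee ids as row names.
#' @export
load_personality_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tab$ratee_id <- as.character(tab$ratee_id)
  personality_wide(tab)
}

#' Load a component-score matrix
#'
#' Reads the deposited PCA-score layout. Orientation is never guessed:
#' state explicitly whether participants are in columns (the deposited
#' layout, transposed on load so ratees end up in rows) or already in rows.
#'
#' @param path CSV path; first column = row labels.
#' @param participants "columns" or "rows".
#' @return numeric ratee x component matrix, ratee ids as row names.
#' @export
load_component_scores <- function(path, participants = c("columns", "rows")) {
  participants <- match.arg(participants)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         row.names = 1)
  M <- as.matrix(tab)
  if (!is.numeric(M)) stop("non-numeric cell in component-score file")
  if (participants == "columns") M <- t(M)
  if (anyDuplicated(rownames(M))) stop("duplicate participant id")
  M
}

#' @rdname load_component_scores
#' @param scores ratee x component matrix to write.
#' @export
write_component_scores <- function(scores, path,
                                   participants = c("columns", "rows")) {
  participants <- match.arg(participants)
  M <- if (participants == "columns") t(scores) else scores
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Produces the same layout the loaders consume: `images/<id>.png`,
#' `landmarks/<id>.pts`, `manifest.csv`, `ratings.csv`, `personality.csv`,
#' `genders.csv`, and the generator's ground truth (`truth.json`: latent
#' factors, seed and the generating parameters).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "landmarks"), showWarnings = FALSE)
  ids <- cohort$genders$ratee_id
  for (id in ids) {
    write_face_png(cohort$images[[id]], file.path(dir, "images", paste0(id, ".png")))
    write_pts(cohort$landmarks[[id]], file.path(dir, "landmarks", paste0(id, ".pts")))
  }
  utils::write.csv(data.frame(ratee_id = ids, gender = cohort$genders$gender,
                              image = file.path("images", paste0(ids, ".png")),
                              landmarks = file.path("landmarks", paste0(ids, ".pts"))),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  write_ratings_csv(cohort$ratings, file.path(dir, "ratings.csv"))
  utils::write.csv(cohort$personality, file.path(dir, "personality.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$genders, file.path(dir, "genders.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         latents = as.data.frame(cohort$latents),
         ratee_id = ids,
         factor_sds = as.list(cohort$spec$factor_sds),
         judge_noise = cohort$spec$judge_noise,
         personality_rho = as.list(cohort$spec$personality_rho)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
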