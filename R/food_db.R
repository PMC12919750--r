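# Food-composition database: CSV ingestion with consistency checks,
# SQLite persistence, suitability queries and food-exchange lookup.

#' Food-group taxonomy
#'
#' Eight groups following the Mexican dietary-guidance plate categories
#' (NOM-043). The order is also the ordinal coding order used by the feature
#' encoder, with the two discouraged groups last.
#'
#' @format Character vector of the eight group codes.
#' @export
food_groups <- c("vegetable", "legume", "fruit", "cereal_tuber",
                 "animal_protein", "dairy", "fats_oils", "sugar_sweet")

foods_columns <- c("food_id", "name", "group", "serving_desc", "serving_g",
                   "kcal", "cho_g", "protein_g", "fat_g", "fiber_g",
                   "glycemic_index", "diabetes_suitable", "regional")

# Atwater consistency: 4 CHO + 4 protein + 9 fat must sit within +/-20% of the
# declared kcal. Absorbs fiber and rounding effects in composition tables.
atwater_tolerance <- 0.20

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

.validate_food_row <- function(row) {
  # returns NULL if valid, otherwise a reason code
  for (col in c("food_id", "name", "group", "serving_g", "kcal",
                "cho_g", "protein_g", "fat_g", "fiber_g")) {
    v <- row[[col]]
    if (is.null(v) || is.na(v) || identical(trimws(as.character(v)), ""))
      return(paste0("missing ", col))
  }
  if (!(row$group %in% food_groups)) return(paste0("unknown group '", row$group, "'"))
  num <- c("serving_g", "kcal", "cho_g", "protein_g", "fat_g", "fiber_g")
  vals <- suppressWarnings(vapply(num, function(c) as.numeric(row[[c]]), 0))
  if (any(is.na(vals))) return(paste0("non-numeric ", num[which(is.na(vals))[1]]))
  if (vals[["serving_g"]] <= 0) return("non-positive serving_g")
  if (any(vals[c("kcal", "cho_g", "protein_g", "fat_g", "fiber_g")] < 0))
    return("negative nutrient value")
  atwater <- 4 * vals[["cho_g"]] + 4 * vals[["protein_g"]] + 9 * vals[["fat_g"]]
  if (abs(atwater - vals[["kcal"]]) > atwater_tolerance * vals[["kcal"]])
    return(sprintf("atwater_inconsistent (macro kcal %.1f vs declared %.1f)",
                   atwater, vals[["kcal"]]))
  gi <- row$glycemic_index
  if (!is.null(gi) && !is.na(gi) && !identical(trimws(as.character(gi)), "")) {
    gi <- suppressWarnings(as.numeric(gi))
    if (is.na(gi)) return("non-numeric glycemic_index")
    if (gi < 0 || gi > 110) return("glycemic_index outside [0, 110]")
  }
  NULL
}

#' Load a food-composition CSV
#'
#' Reads a UTF-8 comma-separated table with the documented column set,
#' validates every row (mandatory fields, positive serving size, glycemic
#' index in \[0, 110\] when present, and Atwater energy consistency: macro
#' kcal within 20% of declared kcal) and returns the accepted rows in input
#' order together with a rejection report.
#'
#' @param path CSV file with columns
#'   `food_id,name,group,serving_desc,serving_g,kcal,cho_g,protein_g,fat_g,fiber_g,glycemic_index,diabetes_suitable,regional`.
#' @param strict if `TRUE` any invalid row aborts the load with an error.
#' @return A list with `foods` (data.frame of accepted rows, typed columns)
#'   and `rejected` (data.frame of `row`, `food_id`, `reason`).
#' @export
load_foods_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) fail("foods CSV not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(foods_columns, names(raw))
  if (length(missing_cols))
    fail("foods CSV missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  keep <- logical(nrow(raw))
  reasons <- character(0); rows <- integer(0); ids <- character(0)
  for (i in seq_len(nrow(raw))) {
    reason <- .validate_food_row(as.list(raw[i, ]))
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      if (strict) fail(sprintf("row %d (%s): %s", i, raw$food_id[i], reason))
      rows <- c(rows, i); ids <- c(ids, raw$food_id[i]); reasons <- c(reasons, reason)
    }
  }
  foods <- raw[keep, foods_columns, drop = FALSE]
  rownames(foods) <- NULL
  for (col in c("serving_g", "kcal", "cho_g", "protein_g", "fat_g", "fiber_g",
                "glycemic_index"))
    foods[[col]] <- suppressWarnings(as.numeric(foods[[col]]))
  foods$diabetes_suitable <- .parse_logical(foods$diabetes_suitable)
  foods$regional <- .parse_logical(foods$regional)
  list(foods = foods,
       rejected = data.frame(row = rows, food_id = ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Load a recipes CSV
#'
#' Long format: one row per recipe component, columns
#' `recipe_id,name,food_id,servings,meal_slots` (meal slots separated by `|`).
#'
#' @param path recipes CSV.
#' @return data.frame of components.
#' @export
load_recipes_csv <- function(path) {
  if (!file.exists(path)) fail("recipes CSV not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("recipe_id", "name", "food_id", "servings", "meal_slots")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    fail("recipes CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  raw$servings <- as.numeric(raw$servings)
  if (any(is.na(raw$servings) | raw$servings < 0)) fail("recipe servings must be >= 0")
  raw
}

#' Create a kiosk food database
#'
#' Writes foods (and optionally recipes) into a single-file SQLite database
#' with tables `foods`, `recipes` and `recipe_components`, then reopens it.
#'
#' @param foods data.frame of validated foods, as from [load_foods_csv()].
#' @param path file path for the SQLite database.
#' @param recipes optional data.frame from [load_recipes_csv()]; every
#'   component `food_id` must resolve to a food.
#' @return An open database handle of class `"food_db"`.
#' @export
init_db <- function(foods, path, recipes = NULL) {
  if (is.null(foods) || nrow(foods) == 0) fail("empty food database")
  dup <- foods$food_id[duplicated(foods$food_id)]
  if (length(dup)) fail("duplicate food_id: ", paste(unique(dup), collapse = ", "))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE foods (
      food_id TEXT PRIMARY KEY, name TEXT NOT NULL, \"group\" TEXT NOT NULL,
      serving_desc TEXT, serving_g REAL NOT NULL, kcal REAL NOT NULL,
      cho_g REAL NOT NULL, protein_g REAL NOT NULL, fat_g REAL NOT NULL,
      fiber_g REAL NOT NULL, glycemic_index REAL,
      diabetes_suitable INTEGER NOT NULL, regional INTEGER NOT NULL)")
  DBI::dbExecute(con, "CREATE TABLE recipes (
      recipe_id TEXT PRIMARY KEY, name TEXT NOT NULL, meal_slots TEXT)")
  DBI::dbExecute(con, "CREATE TABLE recipe_components (
      recipe_id TEXT NOT NULL REFERENCES recipes(recipe_id),
      food_id TEXT NOT NULL REFERENCES foods(food_id),
      servings REAL NOT NULL)")
  stored <- foods
  stored$diabetes_suitable <- as.integer(stored$diabetes_suitable)
  stored$regional <- as.integer(stored$regional)
  DBI::dbWriteTable(con, "foods", stored, append = TRUE)
  if (!is.null(recipes) && nrow(recipes)) {
    unknown <- setdiff(recipes$food_id, foods$food_id)
    if (length(unknown))
      fail("recipe component food_id not in foods: ", paste(unknown, collapse = ", "))
    heads <- unique(recipes[, c("recipe_id", "name", "meal_slots")])
    if (anyDuplicated(heads$recipe_id))
      fail("recipe_id with inconsistent name/meal_slots")
    DBI::dbWriteTable(con, "recipes", heads, append = TRUE)
    DBI::dbWriteTable(con, "recipe_components",
                      recipes[, c("recipe_id", "food_id", "servings")],
                      append = TRUE)
  }
  DBI::dbDisconnect(con)
  ok <- TRUE
  open_db(path)
}

#' Open an existing kiosk food database
#'
#' @param path SQLite file created by [init_db()].
#' @return Handle of class `"food_db"`; close with [close_db()].
#' @export
open_db <- function(path) {
  if (!file.exists(path)) fail("database not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  if (!all(c("foods", "recipes", "recipe_components") %in% DBI::dbListTables(con))) {
    DBI::dbDisconnect(con)
    fail("not a kiosk food database: ", path)
  }
  structure(list(con = con, path = path), class = "food_db")
}

#' @rdname open_db
#' @param db an open `"food_db"` handle.
#' @export
close_db <- function(db) {
  stopifnot(inherits(db, "food_db"))
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' Read all foods back from a database
#'
#' @param db an open `"food_db"` handle.
#' @return data.frame in the same column layout as [load_foods_csv()] output,
#'   in insertion order.
#' @export
db_foods <- function(db) {
  stopifnot(inherits(db, "food_db"))
  out <- DBI::dbGetQuery(db$con, "SELECT * FROM foods ORDER BY rowid")
  out$diabetes_suitable <- as.logical(out$diabetes_suitable)
  out$regional <- as.logical(out$regional)
  out
}

#' Recipe nutrient totals
#'
#' Serving-weighted sum of component nutrients for every stored recipe.
#'
#' @param db an open `"food_db"` handle.
#' @return data.frame with one row per recipe: `recipe_id`, `name`, `kcal`,
#'   `cho_g`, `protein_g`, `fat_g`, `fiber_g`.
#' @export
db_recipe_totals <- function(db) {
  stopifnot(inherits(db, "food_db"))
  DBI::dbGetQuery(db$con, "
    SELECT r.recipe_id, r.name,
           SUM(c.servings * f.kcal)      AS kcal,
           SUM(c.servings * f.cho_g)     AS cho_g,
           SUM(c.servings * f.protein_g) AS protein_g,
           SUM(c.servings * f.fat_g)     AS fat_g,
           SUM(c.servings * f.fiber_g)   AS fiber_g
    FROM recipes r
    JOIN recipe_components c ON c.recipe_id = r.recipe_id
    JOIN foods f ON f.food_id = c.food_id
    GROUP BY r.recipe_id, r.name ORDER BY r.recipe_id")
}

# low-GI-priority ordering shared by queries and the planner:
# GI ascending with missing GI after all present values, then fiber
# descending, then food_id for a total order.
.order_low_gi <- function(foods) {
  gi <- foods$glycemic_index
  gi[is.na(gi)] <- Inf
  order(gi, -foods$fiber_g, foods$food_id)
}

#' Query foods by group with diabetes-suitability filters
#'
#' Returns the foods of one group, optionally restricted to
#' diabetes-suitable items and to a maximum glycemic index, sorted for
#' low-GI priority: GI ascending (items without GI last), fiber descending,
#' ties by `food_id`.
#'
#' @param db an open `"food_db"` handle.
#' @param group one of [food_groups].
#' @param diabetes_only keep only items flagged diabetes-suitable.
#' @param max_gi optional glycemic-index ceiling; items without a GI are
#'   excluded when a ceiling is requested.
#' @return data.frame of matching foods (possibly empty).
#' @export
query_by_group <- function(db, group, diabetes_only = FALSE, max_gi = NULL) {
  stopifnot(inherits(db, "food_db"))
  group <- match_enum(group, food_groups, "food group")
  out <- DBI::dbGetQuery(db$con,
    'SELECT * FROM foods WHERE "group" = ?', params = list(group))
  out$diabetes_suitable <- as.logical(out$diabetes_suitable)
  out$regional <- as.logical(out$regional)
  if (diabetes_only) out <- out[out$diabetes_suitable, , drop = FALSE]
  if (!is.null(max_gi))
    out <- out[!is.na(out$glycemic_index) & out$glycemic_index <= max_gi, ,
               drop = FALSE]
  out <- out[.order_low_gi(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find food-exchange equivalents
#'
#' Standard food-exchange convention: an equivalent is a different food of
#' the same group whose per-serving energy is within a relative tolerance of
#' the query food's energy. Results are sorted by absolute kcal difference.
#'
#' @param db an open `"food_db"` handle.
#' @param food_id the food to substitute.
#' @param kcal_tolerance_fraction relative energy tolerance in (0, 1\];
#'   default 0.10.
#' @return data.frame of equivalent foods sorted by `|delta kcal|` ascending
#'   (ties by `food_id`); possibly empty.
#' @export
find_equivalents <- function(db, food_id, kcal_tolerance_fraction = 0.10) {
  stopifnot(inherits(db, "food_db"))
  if (!is_number(kcal_tolerance_fraction) || kcal_tolerance_fraction <= 0 ||
      kcal_tolerance_fraction > 1)
    fail("kcal_tolerance_fraction must be in (0, 1]")
  query <- DBI::dbGetQuery(db$con, "SELECT * FROM foods WHERE food_id = ?",
                           params = list(food_id))
  if (nrow(query) == 0) fail("unknown food_id: ", food_id)
  cand <- DBI::dbGetQuery(db$con,
    'SELECT * FROM foods WHERE "group" = ? AND food_id != ?',
    params = list(query$group, food_id))
  cand$diabetes_suitable <- as.logical(cand$diabetes_suitable)
  cand$regional <- as.logical(cand$regional)
  delta <- abs(cand$kcal - query$kcal)
  keep <- delta <= kcal_tolerance_fraction * query$kcal
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(abs(cand$kcal - query$kcal), cand$food_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' @export
print.food_db <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM foods")$n
  r <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM recipes")$n
  cat(sprintf("<food_db> %s: %d foods, %d recipes\n", x$path, n, r))
  invisible(x)
}

#' Path to the bundled illustrative regional food table
#'
#' A small synthetic-but-plausible table of regional Mexican foods used in
#' examples and tests. Nutrient values are illustrative, not an authoritative
#' composition source.
#'
#' @return File path of the CSV inside the installed package.
#' @export
kiosk_foods_csv <- function() {
  system.file("extdata", "foods_mx_synthetic.csv", package = "nutrikiosk",
              mustWork = TRUE)
}
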