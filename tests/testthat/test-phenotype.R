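dicts <- codeDictionaries()

rec <- function(codes = "G35", meds = character(), phq = NULL, ...) {
  patientRecord("X", icd10Codes = codes, medications = meds, phqObs = phq,
                mriDates = as.Date("2015-06-01"), ...)
}
phq0 <- data.frame(instrument = "PHQ2", score = 0L,
                   date = as.Date("2015-05-01"))

test_that("anxiety stratification follows the dx/med/PHQ rules", {
  expect_equal(
    classifyAnxiety(rec(c("G35", "F41.1"), "sertraline"), dicts)$label,
    "mild")  # sertraline is not in the anxiolytic list: dx only
  expect_equal(
    classifyAnxiety(rec(c("G35", "F41.1"), "lorazepam"), dicts)$label,
    "severe")
  expect_equal(classifyAnxiety(rec(c("G35", "F40.0")), dicts)$label, "mild")
  expect_equal(classifyAnxiety(rec(meds = "buspirone"), dicts)$label, "mild")
  expect_equal(classifyAnxiety(rec(phq = phq0), dicts)$label, "none")
  expect_equal(classifyAnxiety(rec(), dicts)$label, "excluded")
  # nonzero PHQ blocks the asymptomatic label
  phq1 <- data.frame(instrument = "PHQ9", score = 3L,
                     date = as.Date("2015-05-01"))
  expect_equal(classifyAnxiety(rec(phq = phq1), dicts)$label, "excluded")
  # psychiatric code outside the anxiety block also blocks it
  expect_equal(classifyAnxiety(rec(c("G35", "F32.9"), phq = phq0),
                               dicts)$label, "excluded")
  expect_error(classifyAnxiety(rec(c("G35", "bad code!")), dicts),
               "malformed")
})

test_that("severity rules are monotone and reversible in the anxiolytic", {
  base <- rec(c("G35", "F40.0"))
  expect_equal(classifyAnxiety(base, dicts)$label, "mild")
  up <- rec(c("G35", "F40.0"), meds = dicts$anxiolyticMeds[1])
  expect_equal(classifyAnxiety(up, dicts)$label, "severe")
  down <- rec(c("G35", "F40.0"))
  expect_equal(classifyAnxiety(down, dicts)$label, "mild")
})

test_that("classification depends only on the record-dictionary overlap", {
  a <- rec(c("G35", "F41.1"), meds = c("lorazepam", "metformin"))
  b <- rec(c("G35", "F41.1", "I10", "M54.5"),
           meds = c("lorazepam", "lisinopril"))
  expect_equal(classifyAnxiety(a, dicts)$label,
               classifyAnxiety(b, dicts)$label)
  # swapping the dictionary redefines the outcome
  alt <- codeDictionaries(anxietyDxPrefixes = "F99",
                          anxiolyticMeds = "metformin")
  expect_equal(classifyAnxiety(a, alt)$label, "mild")
})

test_that("labels partition randomized records", {
  set.seed(99)
  labs <- replicate(400, classifyAnxiety(randomRecord(dicts), dicts)$label)
  expect_true(all(labs %in% c("none", "mild", "severe", "excluded")))
  # severe <=> dx & med, checked via the reported basis
  for (i in 1:100) {
    r <- randomRecord(dicts)
    a <- classifyAnxiety(r, dicts)
    expect_equal(a$label == "severe",
                 unname(a$basis["has_anx_dx"] && a$basis["has_anxiolytic"]))
    expect_equal(a$label == "mild",
                 unname(xor(a$basis["has_anx_dx"], a$basis["has_anxiolytic"])))
  }
})

test_that("depression phenotype is binary with the shared asymptomatic rule", {
  expect_equal(classifyDepression(rec(phq = phq0), dicts), "no_depression")
  expect_equal(classifyDepression(rec(c("G35", "F33.1")), dicts),
               "depression")
  expect_equal(classifyDepression(rec(meds = "fluoxetine"), dicts),
               "depression")
  expect_equal(classifyDepression(rec(), dicts), "excluded")
})

test_that("PROMIS summaries average the right domains at the right date", {
  mkObs <- function(scores, dates = as.Date("2015-06-01")) {
    data.frame(domain = names(scores), score = unname(scores), date = dates)
  }
  phys <- c(physical_health = 40, physical_activities = 50, fatigue = 60,
            physical_impairment = 50)
  emot <- c(mental_health_mood = 30, emotional_problems = 30,
            quality_of_life = 30, social_satisfaction = 30,
            social_activities = 30, mental_impairment = 30)
  r <- rec(phq = phq0)
  r@promisObs <- mkObs(c(phys, emot))
  s <- promisSummaries(r, as.Date("2015-06-01"))
  expect_equal(s$physical, 50)
  expect_equal(s$emotional, 30)
  expect_equal(s$n_physical_domains, 4L)
  expect_equal(s$n_emotional_domains, 6L)

  # all domains equal -> both summaries equal
  r@promisObs <- mkObs(setNames(rep(50, 10), names(c(phys, emot))))
  s2 <- promisSummaries(r)
  expect_equal(s2$physical, 50); expect_equal(s2$emotional, 50)

  # proximity rule: 3-day observation beats the 200-day one
  r@promisObs <- data.frame(
    domain = "fatigue", score = c(10, 90),
    date = as.Date("2015-06-01") + c(200, 3))
  s3 <- promisSummaries(r, as.Date("2015-06-01"))
  expect_equal(s3$physical, 90)
  expect_true(s3$incomplete)  # emotional side empty
  expect_true(is.na(s3$emotional))
})

test_that("first MRI selection takes the chronological minimum", {
  r <- rec(phq = phq0)
  r@mriDates <- as.Date(c("2015-03-01", "2012-07-11"))
  expect_equal(selectFirstMri(r), as.Date("2012-07-11"))
  r@mriDates <- as.Date(c("2012-07-11", "2012-07-11"))
  expect_equal(selectFirstMri(r), as.Date("2012-07-11"))
  r@mriDates <- as.Date(character())
  expect_error(selectFirstMri(r), "no MRI dates")
})

test_that("records labelled none have all-zero PHQ by construction", {
  co <- makeCohort(synthConfig(nPatients = 80, seed = 4,
                               phqMissingRate = 0), imaging = FALSE)
  st <- classifyCohort(co$records)
  none <- st[st$anxiety == "none", ]
  expect_gt(nrow(none), 0)
  expect_true(all(none$phq2 == 0))
  expect_equal(mean(none$phq2), 0)
})
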