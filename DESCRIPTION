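Package: traitgroups
Title: Do A Priori Plant Functional Groups Capture Species Trait Variation?
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate how well a priori plant functional group
    classifications (evergreen shrubs, deciduous shrubs, graminoids, forbs and
    finer schemes) explain species-level variation in plant functional traits,
    compared with post hoc trait-based clustering. Provides cleaning and
    standardization of long-format trait records, species-by-trait matrix
    construction, distance-based variance partitioning (one-way PERMANOVA with
    permutation inference and exact enumeration for small designs), principal
    components analysis of trait space, k-means and Ward agglomerative
    clustering, an optimal label-matching consistency statistic with
    abundance weighting from plot cover data, an exhaustive trait-subset
    resampling analysis of variance explained, and a synthetic trait-database
    generator with planted group structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan, mclust, withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
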