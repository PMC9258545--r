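Package: hapscan
Title: Haplotype-Feature Analysis of Admixed Populations with
    Simulation-Calibrated Selection Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the haplotype structure of recently
    admixed and bottlenecked populations from phased diploid genotypes:
    linkage-disequilibrium decay profiles, identity-by-descent segment
    detection (seed-and-extend) with a normalised IBD sharing score and
    weighted block-jackknife confidence intervals, PLINK-style
    runs-of-homozygosity calling, Nei haplotype diversity and expected
    heterozygosity, and an EHH/iHS selection scan whose significance
    cutoffs are derived from a built-in forward Wright-Fisher simulator
    of a colonisation-bottleneck-plus-admixture demography. Candidate
    alleles can be dated with the haplotype-decay TMRCA clock.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Coverage
RoxygenNote: 7.3.3
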