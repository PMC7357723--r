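Package: ssnmrice
Title: Site-Specific Nutrient Management Recommendations for Irrigated Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Field-specific fertilizer N, P and K recommendations for
    irrigated rice using site-specific nutrient management (SSNM)
    principles, as deployed in the Cauvery Delta (Tamil Nadu, India)
    rice system. Sets a per-field target yield from the farmer's
    reported historical yield and a varietal baseline window, computes
    the N rate from the targeted yield gain and an agronomic
    efficiency, the P rate by full maintenance (fertilizer P equals
    estimated crop removal) and the K rate by partial maintenance
    (removal minus irrigation-water and residue K inputs plus an
    allowed soil-K drawdown), schedules split applications at three
    critical growth stages, and converts elemental rates into masses of
    farmer-selected commercial fertilizer products with urea topping up
    N. Companion tools compute on-farm trial economics (fertilizer
    cost, partial factor productivity of N, gross return above
    fertilizer cost, added net benefit, financial-risk exceedance
    curves) and post-hoc P and K input-output balances, and generate
    synthetic trial populations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
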