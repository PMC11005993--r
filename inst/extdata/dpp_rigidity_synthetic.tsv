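# property_name: rigidity
# step_size: 4
# units: dimensionless (inverse Olson deformability, composite)
# source: SYNTHETIC stand-in: mean of 10/deformability over the three dinucleotide steps of each tetranucleotide (deformability from Olson et al. 1998); not a published tetranucleotide rigidity scale
AAAA	3.448
AAAC	3.748
AAAG	3.886
AAAT	4.382
AACA	2.939
AACC	3.145
AACG	2.874
AACT	4.186
AAGA	3.478
AAGC	3.57
AAGG	3.283
AAGT	4.186
AATA	3.762
AATC	3.974
AATG	3.573
AATT	4.382
ACAA	2.939
ACAC	3.239
ACAG	3.377
ACAT	3.873
ACCA	2.336
ACCC	2.542
ACCG	2.271
ACCT	3.583
ACGA	2.466
ACGC	2.558
ACGG	2.271
ACGT	3.174
ACTA	3.566
ACTC	3.777
ACTG	3.377
ACTT	4.186
AGAA	3.478
AGAC	3.777
AGAG	3.915
AGAT	4.411
AGCA	2.761
AGCC	2.967
AGCG	2.696
AGCT	4.008
AGGA	2.874
AGGC	2.967
AGGG	2.68
AGGT	3.583
AGTA	3.566
AGTC	3.777
AGTG	3.377
AGTT	4.186
ATAA	3.762
ATAC	4.062
ATAG	4.2
ATAT	4.696
ATCA	3.164
ATCC	3.37
ATCG	3.1
ATCT	4.411
ATGA	3.164
ATGC	3.257
ATGG	2.97
ATGT	3.873
ATTA	3.762
ATTC	3.974
ATTG	3.573
ATTT	4.382
CAAA	2.639
CAAC	2.939
CAAG	3.077
CAAT	3.573
CACA	2.13
CACC	2.336
CACG	2.065
CACT	3.377
CAGA	2.668
CAGC	2.761
CAGG	2.474
CAGT	3.377
CATA	2.953
CATC	3.164
CATG	2.764
CATT	3.573
CCAA	2.036
CCAC	2.336
CCAG	2.474
CCAT	2.97
CCCA	1.433
CCCC	1.639
CCCG	1.368
CCCT	2.68
CCGA	1.563
CCGC	1.655
CCGG	1.368
CCGT	2.271
CCTA	2.663
CCTC	2.874
CCTG	2.474
CCTT	3.283
CGAA	2.166
CGAC	2.466
CGAG	2.603
CGAT	3.1
CGCA	1.449
CGCC	1.655
CGCG	1.384
CGCT	2.696
CGGA	1.563
CGGC	1.655
CGGG	1.368
CGGT	2.271
CGTA	2.254
CGTC	2.466
CGTG	2.065
CGTT	2.874
CTAA	3.266
CTAC	3.566
CTAG	3.704
CTAT	4.2
CTCA	2.668
CTCC	2.874
CTCG	2.603
CTCT	3.915
CTGA	2.668
CTGC	2.761
CTGG	2.474
CTGT	3.377
CTTA	3.266
CTTC	3.478
CTTG	3.077
CTTT	3.886
GAAA	3.04
GAAC	3.339
GAAG	3.478
GAAT	3.974
GACA	2.53
GACC	2.736
GACG	2.466
GACT	3.777
GAGA	3.069
GAGC	3.161
GAGG	2.874
GAGT	3.777
GATA	3.353
GATC	3.565
GATG	3.164
GATT	3.974
GCAA	2.323
GCAC	2.623
GCAG	2.761
GCAT	3.257
GCCA	1.72
GCCC	1.926
GCCG	1.655
GCCT	2.967
GCGA	1.85
GCGC	1.942
GCGG	1.655
GCGT	2.558
GCTA	2.95
GCTC	3.161
GCTG	2.761
GCTT	3.57
GGAA	2.437
GGAC	2.736
GGAG	2.874
GGAT	3.37
GGCA	1.72
GGCC	1.926
GGCG	1.655
GGCT	2.967
GGGA	1.834
GGGC	1.926
GGGG	1.639
GGGT	2.542
GGTA	2.525
GGTC	2.736
GGTG	2.336
GGTT	3.145
GTAA	3.128
GTAC	3.428
GTAG	3.566
GTAT	4.062
GTCA	2.53
GTCC	2.736
GTCG	2.466
GTCT	3.777
GTGA	2.53
GTGC	2.623
GTGG	2.336
GTGT	3.239
GTTA	3.128
GTTC	3.339
GTTG	2.939
GTTT	3.748
TAAA	2.828
TAAC	3.128
TAAG	3.266
TAAT	3.762
TACA	2.318
TACC	2.525
TACG	2.254
TACT	3.566
TAGA	2.857
TAGC	2.95
TAGG	2.663
TAGT	3.566
TATA	3.142
TATC	3.353
TATG	2.953
TATT	3.762
TCAA	2.23
TCAC	2.53
TCAG	2.668
TCAT	3.164
TCCA	1.627
TCCC	1.834
TCCG	1.563
TCCT	2.874
TCGA	1.757
TCGC	1.85
TCGG	1.563
TCGT	2.466
TCTA	2.857
TCTC	3.069
TCTG	2.668
TCTT	3.478
TGAA	2.23
TGAC	2.53
TGAG	2.668
TGAT	3.164
TGCA	1.514
TGCC	1.72
TGCG	1.449
TGCT	2.761
TGGA	1.627
TGGC	1.72
TGGG	1.433
TGGT	2.336
TGTA	2.318
TGTC	2.53
TGTG	2.13
TGTT	2.939
TTAA	2.828
TTAC	3.128
TTAG	3.266
TTAT	3.762
TTCA	2.23
TTCC	2.437
TTCG	2.166
TTCT	3.478
TTGA	2.23
TTGC	2.323
TTGG	2.036
TTGT	2.939
TTTA	2.828
TTTC	3.04
TTTG	2.639
TTTT	3.448
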