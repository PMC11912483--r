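24
4-unit synthetic helical chain (units: Angstrom)
X 1.05835442134 0 0
X 0.74084809493799997 0.74084809493799997 0.37042404746899998
X 0 1.05835442134 0.74084809493799997
X -0.74084809493799997 0.74084809493799997 1.111272142407
H 1.5346139109429999 0 0.18521202373449999
H 0 1.5346139109429999 0.92606011867250004
X -0.18378131659142954 1.0422756395703812 1.4816961898759999
X -0.85823986931326735 0.60094602608526604 1.8521202373450001
X -1.0422756395703812 -0.18378131659142954 2.2225442848139996
X -0.60094602608526604 -0.85823986931326735 2.5929683322830002
H -0.26648290905757283 1.5112996773770524 1.6669082136105
H -1.5112996773770524 -0.26648290905757283 2.4077563085485001
X -0.99452783990933824 -0.36197853087606191 2.9633923797519999
X -0.4427845163232933 -0.94955445954978002 3.333816427221
X 0.36197853087606191 -0.99452783990933824 3.7042404746900002
X 0.94955445954978002 -0.44278451632329335 4.0746645221589999
H -1.4420653678685404 -0.52486886977028979 3.1486044034864995
H 0.52486886977028979 -1.4420653678685404 3.8894524984244998
X 0.52917721067000012 -0.91656181508801937 4.4450885696279991
X 1.0120173180306136 -0.27116922309261349 4.8155126170969993
X 0.91656181508801937 0.52917721067000012 5.1859366645659994
X 0.27116922309261349 1.0120173180306136 5.5563607120349996
H 0.76730695547150007 -1.3290146318776279 4.6303005933624988
H 1.3290146318776279 0.76730695547150007 5.3711486883004991
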