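# Default country -> area-set table for the nine-area scheme.
# Countries listed with more than one area are deliberately ambiguous and
# never resolve via the country route of the assignment cascade.
# Fully user-overridable; this default covers the examples and tests.
Guyana: TSA
Brazil: TSA
Venezuela: TSA
Suriname: TSA
Ecuador: And
Peru: And
Bolivia: And
Colombia: [And, TSA]
Chile: [And, Pat]
Argentina: [And, Pat]
Belize: CAm
Guatemala: CAm
Costa Rica: CAm
Panama: CAm
Cuba: CAm
Dominican Republic: CAm
Mexico: [CAm, Nea]
USA: Nea
Canada: Nea
France: Pal
Germany: Pal
Sweden: Pal
Finland: Pal
Estonia: Pal
Russia: Pal
Japan: Pal
China: [Pal, Ind]
India: Ind
Thailand: Ind
Malaysia: Ind
Indonesia: [Ind, Aus]
Australia: Aus
New Zealand: Aus
Papua New Guinea: Aus
Cameroon: Afr
Tanzania: Afr
Zambia: Afr
Madagascar: Afr
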