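# Synthetic reconstruction of the 22-ecoregion zonation of Yunnan
# (5 climate zones: I northern tropical, II southern subtropical,
#  III medium tropical/plateau, IV Northeast-Yunnan, V Northwest-Yunnan
#  subalpine; 3+5+11+2+1 ecoregions).  Codes IIIA5 and IIIB1/IIIB4/IIIB5
# and the east/west assignment of unattested ecoregions are inferred, not
# attested; treat this file as a template configuration, not reference data.
area	climate_zone	side
IA1	I	west
IA2	I	west
IB1	I	east
IIA1	II	west
IIA2	II	west
IIA3	II	west
IIB1	II	east
IIB2	II	east
IIIA1	III	west
IIIA2	III	west
IIIA3	III	west
IIIA4	III	west
IIIA5	III	west
IIIB1	III	east
IIIB2	III	east
IIIB3	III	east
IIIB4	III	east
IIIB5	III	east
IIIB6	III	east
IVA1	IV	east
IVA2	IV	east
VA1	V	west
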