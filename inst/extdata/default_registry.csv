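id,name,countries,mtdna,nudna,certainty,suture_zone,hybrid_origin,managed_metapopulation,extant,notes
SN_niokolo,Niokolo-Koba,SN,west,west,fairly_high,none,FALSE,FALSE,TRUE,westernmost extant population
WAP,W-Arly-Pendjari complex,BF|NE|BJ,west,west,high,none,FALSE,FALSE,TRUE,largest West African stronghold; transboundary
NG_west,Nigeria west (Kainji),NG,west,west,medium,none,FALSE,FALSE,TRUE,west of the Niger split
NG_east,Nigeria east (Yankari),NG,central,central,medium,none,FALSE,FALSE,TRUE,east of the Niger split
CM_north,Cameroon north,CM,central,central,high,none,FALSE,FALSE,TRUE,
TD_south,Chad south,TD,central,central,medium,none,FALSE,FALSE,TRUE,
CF_north,Central African Republic,CF,central,central,medium,none,FALSE,FALSE,TRUE,
GA_bateke,Gabon Bateke Plateau,GA,south west,southern,medium,none,FALSE,FALSE,TRUE,recently rediscovered; South West haplogroup from mitogenome evidence
SZ1_block,Sudan-South Sudan-Ethiopia suture,SD|SS|ET,central|north east,central|east,medium,SZ1,FALSE,FALSE,TRUE,natural overlap of the two subspecies
CD_northeast,DRC north-east,CD,north east,east,medium,none,FALSE,FALSE,TRUE,
CD_central,DRC central-west,CD,central,central,medium,none,FALSE,FALSE,TRUE,release-site-dependent clade within DRC
UG_block,Uganda,UG,north east,east,medium,none,FALSE,FALSE,TRUE,possible internal clade boundary
KE_north,Kenya north,KE,north east,east,fairly_high,none,FALSE,FALSE,TRUE,north of the Kenyan split
KE_south,Kenya south,KE,east/southern,east,high,none,FALSE,FALSE,TRUE,south of the Kenyan split
KE_nakuru,Lake Nakuru-Soysambu,KE,east/southern|north east,east,high,none,TRUE,FALSE,TRUE,founders partly from Aberdares; human-mediated admixture
TZ_block,Tanzania,TZ,east/southern,east,high,none,FALSE,FALSE,TRUE,
SZ2_block,Zambia-Malawi-Mozambique suture,ZM|MW|MZ,east/southern,east|southern,medium,SZ2,FALSE,FALSE,TRUE,natural overlap of East and Southern nuclear clades
ZM_kaza,Zambia KAZA sector,ZM,east/southern|south west,southern,fairly_high,none,FALSE,FALSE,TRUE,mtDNA haplogroup overlap; not a suture zone
MW_restored,Malawi restored (Liwonde & Majete),MW,east/southern|south west,southern,high,none,TRUE,FALSE,TRUE,restocked from South African managed metapopulation
MZ_south,Mozambique south,MZ,east/southern,southern,fairly_high,none,FALSE,FALSE,TRUE,
RW_akagera,Rwanda Akagera,RW,east/southern|south west,southern,high,none,TRUE,FALSE,TRUE,restored 2015 from South African managed metapopulation
BW_kaza,Botswana Okavango-Chobe,BW,south west|east/southern,southern,high,none,FALSE,FALSE,TRUE,KAZA mtDNA haplogroup overlap
NA_etosha,Namibia Etosha and north-west,NA,south west,southern,high,none,FALSE,FALSE,TRUE,
NA_kaza,Namibia Zambezi (KAZA),NA,south west|east/southern,southern,fairly_high,none,FALSE,FALSE,TRUE,KAZA mtDNA haplogroup overlap
AO_block,Angola,AO,south west,southern,medium,none,FALSE,FALSE,TRUE,
ZW_block,Zimbabwe,ZW,east/southern|south west,southern,high,none,TRUE,FALSE,TRUE,potentially hybrid lions from South Africa
ZA_kruger,South Africa Kruger area,ZA,east/southern|south west,southern,high,none,TRUE,FALSE,TRUE,South West haplotype introgressed from Etosha founders
ZA_kgalagadi,Kgalagadi Transfrontier Park,ZA|BW,south west,southern,high,none,FALSE,FALSE,TRUE,transboundary
ZA_metapop,South Africa managed metapopulation,ZA,east/southern|south west,southern,high,none,TRUE,TRUE,TRUE,W2 stock; mix of East/Southern and South West haplogroups
SZ_hlane,Eswatini Hlane Royal NP,SZ,east/southern|south west,southern,high,none,TRUE,FALSE,TRUE,restored from South African stock
IN_gir,India Gir landscape,IN,india,india,high,none,FALSE,FALSE,TRUE,nested within P. l. leo; strongly differentiated
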