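code,name,province,autonomous_community,surface_ha,population,centroid_lat,centroid_lon
08001,Abrera,Barcelona,Cataluña,1998,12853,41.517,1.901
08019,Barcelona,Barcelona,Cataluña,10135,1655956,41.390,2.154
08279,Sant Cugat del Vallès,Barcelona,Cataluña,4832,95725,41.473,2.081
17079,Girona,Girona,Cataluña,3914,103369,41.979,2.821
17118,Olot,Girona,Cataluña,2938,36616,42.182,2.489
46250,València,Valencia,Comunitat Valenciana,13465,807693,39.470,-0.377
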