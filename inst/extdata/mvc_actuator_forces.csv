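condition,pos,trial,phi_deg,force_N
original_static,1,1,15,1909.0
original_static,1,2,15,1852.9
original_static,2,1,30,1421.3
original_static,2,2,30,1412.7
original_static,3,1,45,1338.5
original_static,3,2,45,1313.9
original_static,4,1,60,1127.9
original_static,4,2,60,1179.7
original_phys,1,1,15,1912.4
original_phys,1,2,15,1857.9
original_phys,2,1,30,1426.1
original_phys,2,2,30,1415.8
original_phys,3,1,45,1339.0
original_phys,3,2,45,1309.5
original_phys,4,1,60,1165.6
original_phys,4,2,60,1203.9
optimized_phys,1,1,15,1957.3
optimized_phys,1,2,15,1882.8
optimized_phys,2,1,30,1865.9
optimized_phys,2,2,30,1774.1
optimized_phys,3,1,45,1853.7
optimized_phys,3,2,45,1809.7
optimized_phys,4,1,60,1892.4
optimized_phys,4,2,60,1916.1
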